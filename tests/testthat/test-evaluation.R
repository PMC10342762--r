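test_that("confusion counts equal a per-patient tally", {
  set.seed(71)
  truth <- sample(c("negative", "positive"), 100, replace = TRUE)
  pred <- sample(c("negative", "positive"), 100, replace = TRUE)
  cc <- confusion_counts(pred, truth)
  tally <- table(pred = pred, truth = truth)
  expect_equal(cc$tp, unname(tally["positive", "positive"]))
  expect_equal(cc$tn, unname(tally["negative", "negative"]))
  expect_equal(cc$fp, unname(tally["positive", "negative"]))
  expect_equal(cc$fn, unname(tally["negative", "positive"]))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 100)
  self <- confusion_counts(truth, truth)
  expect_equal(self$fp + self$fn, 0)
  expect_error(confusion_counts(pred[1:5], truth), "equal length")
})

test_that("derived metrics reproduce the published operating points", {
  # every printed cell of the reference table, both cohorts, all five models
  ref <- reference_confusion_counts()
  for (i in seq_len(nrow(ref))) {
    m <- metrics_from_counts(ref[i, c("tp", "tn", "fp", "fn")])
    for (metric in c("npv", "ppv", "specificity", "sensitivity", "accuracy")) {
      expect_equal(unname(m$pct[[metric]]), ref[[metric]][i],
                   info = sprintf("%s/%s/%s", ref$set[i], ref$model[i], metric))
    }
  }
  perfect <- metrics_from_counts(list(tp = 40, tn = 60, fp = 0, fn = 0))
  expect_true(all(perfect$pct == 100))
  und <- metrics_from_counts(list(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_true(is.na(und$ppv)) # undefined, not zero
  expect_error(metrics_from_counts(list(tp = -1, tn = 0, fp = 0, fn = 0)),
               "non-negative")
})

test_that("roc curve sweeps thresholds with the >= convention", {
  scores <- c(0.9, 0.8, 0.3, 0.2)
  truth <- c("positive", "positive", "negative", "negative")
  roc <- roc_curve(scores, truth)
  expect_equal(roc$auc, 1)
  # optimal threshold separates perfectly and favours sensitivity on ties
  expect_equal(roc$optimal_threshold, 0.8)
  expect_error(roc_curve(scores, rep("positive", 4)), "both classes")
  expect_error(roc_curve(c(scores[1:3], Inf), truth), "finite")
})

test_that("auc equals the Mann-Whitney statistic and survives monotone maps", {
  set.seed(73)
  for (rep in 1:10) {
    scores <- round(runif(50), 2) # rounding forces ties
    truth <- sample(c("negative", "positive"), 50, replace = TRUE,
                    prob = c(0.4, 0.6))
    if (length(unique(truth)) < 2) next
    auc <- roc_curve(scores, truth)$auc
    expect_equal(auc, mann_whitney_auc(scores, truth), tolerance = 1e-12)
    # strictly monotone transformation leaves the AUC unchanged
    expect_equal(roc_curve(qlogis((scores + 0.5) / 2), truth)$auc, auc,
                 tolerance = 1e-12)
  }
})

test_that("auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(79)
  scores <- runif(200)
  truth <- ifelse(runif(200) < plogis(3 * scores - 1.5), "positive", "negative")
  ours <- roc_curve(scores, truth)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores,
    levels = c("negative", "positive"), direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("random scores give chance-level auc", {
  set.seed(83)
  scores <- runif(2000)
  truth <- sample(c("negative", "positive"), 2000, replace = TRUE)
  auc <- roc_curve(scores, truth)$auc
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
})

test_that("decision-curve closed forms hold", {
  set.seed(89)
  truth <- sample(c("negative", "positive"), 120, replace = TRUE)
  labels <- sample(c("negative", "positive"), 120, replace = TRUE)
  dca <- decision_curve(labels, truth, thresholds = c(0.25, 0.5, 0.75))
  expect_true(all(dca$curve$treat_none == 0))
  cc <- confusion_counts(labels, truth)
  # at p_t = 0.5 the odds weight is 1: NB = (TP - FP) / n
  expect_equal(dca$curve$net_benefit[dca$curve$threshold == 0.5],
               (cc$tp - cc$fp) / 120)
  # treat-all tends to prevalence as p_t -> 0
  tiny <- decision_curve(labels, truth, thresholds = 0.001)
  expect_equal(tiny$curve$treat_all, mean(truth == "positive"),
               tolerance = 1e-2)
  expect_error(decision_curve(labels, truth, thresholds = c(0.5, 1)),
               "inside")
  # model net benefit never beats treat-all and perfect information together
  scores <- runif(120)
  dca2 <- decision_curve(scores, truth)
  perfect <- mean(truth == "positive")
  expect_true(all(dca2$curve$net_benefit <=
                    pmax(dca2$curve$treat_all, perfect) + 1e-12))
})

test_that("logistic baseline recovers generating coefficients", {
  set.seed(97)
  n <- 5000
  coh <- random_records(n, seed = 98)
  beta <- c(intercept = -2.2, psa_density = 9, dre = 1.1, pirads = 0.35)
  eta <- beta["intercept"] + beta["psa_density"] * coh$psa_density +
    beta["dre"] * (coh$dre == "positive") + beta["pirads"] * coh$pirads
  coh$label <- ifelse(runif(n) < plogis(eta), "positive", "negative")
  lr <- fit_lr_baseline(coh, variables = c("psa_density", "dre", "pirads"))
  est <- summary(lr$fit)$coefficients
  for (nm in c("psa_density", "drepositive", "pirads")) {
    truth_val <- switch(nm, psa_density = beta[["psa_density"]],
                        drepositive = beta[["dre"]], pirads = beta[["pirads"]])
    expect_lt(abs(est[nm, "Estimate"] - truth_val),
              3 * est[nm, "Std. Error"], label = nm)
  }
  # null-signal cohort: training AUC near chance
  coh$label <- sample(c("negative", "positive"), n, replace = TRUE)
  lr0 <- fit_lr_baseline(coh, variables = c("psa_density", "dre", "pirads"))
  expect_lt(abs(lr0$roc$auc - 0.5), 0.05)
})

test_that("univariate baselines use the equal-or-greater convention", {
  coh <- data.frame(psa = c(3.45, 3.44), psa_density = c(0.10, 0.099),
                    pirads = c(3, 4))
  expect_identical(univariate_baseline(coh, "psa", 3.45),
                   c("positive", "negative"))
  expect_identical(univariate_baseline(coh, "psa_density", 0.10),
                   c("positive", "negative"))
  expect_identical(univariate_baseline(coh, "pirads", 4),
                   c("negative", "positive"))
  coh$psa[1] <- NA
  expect_error(univariate_baseline(coh, "psa", 3.45), "missing")
})

test_that("evaluate_models reports all five models on both sets", {
  train <- generate_synthetic_cohort(cohort_spec(n = 400, seed = 111))
  test <- generate_synthetic_cohort(cohort_spec(n = 120, prevalence = 0.65,
                                                seed = 112))
  fit <- fit_cascade(train, som_cfg = som_config(epochs = 10, seed = 13))
  ev <- evaluate_models(fit, train, test)
  expect_setequal(unique(ev$metrics$model),
                  c("fis_svm", "lr", "psa", "psa_density", "pirads"))
  expect_setequal(unique(ev$metrics$set), c("training", "validation"))
  expect_equal(nrow(ev$metrics), 10L)
  with(ev$metrics, expect_true(all(tp + tn + fp + fn ==
                                     ifelse(set == "training", 400, 120))))
  expect_length(ev$auc, 5L)
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
})
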