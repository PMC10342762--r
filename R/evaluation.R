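# Evaluation battery: confusion counts, derived metrics, ROC with optimal
# threshold, decision-curve analysis, and the comparator models (logistic
# regression on the six variables; univariate PSA / PSA-density / PI-RADS
# thresholds).

#' Round half up
#'
#' Rounding with ties away from zero (the convention of the printed reports),
#' unlike base [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Confusion counts
#'
#' Tallies true/false positives and negatives; "positive" means disease
#' present at biopsy.
#'
#' @param predictions Predicted labels (`negative`/`positive`).
#' @param truth True labels.
#' @return Object of class `confusion_counts`: `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth must have equal length")
  }
  if (any(!truth %in% c("negative", "positive"))) {
    stop("truth labels must be negative/positive")
  }
  counts <- list(
    tp = sum(predictions == "positive" & truth == "positive"),
    tn = sum(predictions == "negative" & truth == "negative"),
    fp = sum(predictions == "positive" & truth == "negative"),
    fn = sum(predictions == "negative" & truth == "positive")
  )
  class(counts) <- "confusion_counts"
  counts
}

#' Metrics derived from confusion counts
#'
#' NPV = TN/(TN+FN), PPV = TP/(TP+FP), specificity = TN/(TN+FP),
#' sensitivity = TP/(TP+FN), accuracy = (TP+TN)/total. Metrics whose
#' denominator is zero are reported as `NA` (undefined), not 0. Percentages
#' are rounded half-up to one decimal, the convention of the printed reports.
#'
#' @param counts A [confusion_counts()] object or a list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @return Object of class `metrics_report`: the counts, each metric as a
#'   fraction, and a `pct` vector of 1-decimal percentages.
#' @examples
#' m <- metrics_from_counts(list(tp = 759, tn = 238, fp = 385, fn = 65))
#' m$pct[["npv"]] # 78.5
#' @export
metrics_from_counts <- function(counts) {
  with(counts, {
    if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative")
    safe <- function(num, den) if (den > 0) num / den else NA_real_
    frac <- c(
      npv = safe(tn, tn + fn),
      ppv = safe(tp, tp + fp),
      specificity = safe(tn, tn + fp),
      sensitivity = safe(tp, tp + fn),
      accuracy = safe(tp + tn, tp + tn + fp + fn)
    )
    out <- list(counts = list(tp = tp, tn = tn, fp = fp, fn = fn),
                npv = frac[["npv"]], ppv = frac[["ppv"]],
                specificity = frac[["specificity"]],
                sensitivity = frac[["sensitivity"]],
                accuracy = frac[["accuracy"]],
                pct = round_half_up(100 * frac, 1))
    class(out) <- "metrics_report"
    out
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d\n", x$counts$tp, x$counts$tn,
              x$counts$fp, x$counts$fn))
  cat(paste(sprintf("%s %.1f%%", names(x$pct), x$pct), collapse = "  "), "\n")
  invisible(x)
}

#' ROC curve, AUC and optimal threshold
#'
#' Sweeps every unique score as a candidate threshold with the convention
#' that values equal to or greater than the threshold are called positive.
#' AUC is computed by the trapezoid rule over the resulting (FPR, TPR)
#' points. The optimal threshold maximizes Youden's J = sensitivity +
#' specificity - 1 (switchable to the point closest to (0, 1)); among ties
#' the lowest threshold is taken, favouring sensitivity.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param truth True labels (`negative`/`positive`; both classes required).
#' @param criterion Optimal-threshold criterion: `"youden"` or
#'   `"closest_topleft"`.
#' @return Object of class `roc_curve`: `curve` (data frame of threshold,
#'   fpr, tpr), `auc`, `optimal_threshold`.
#' @export
roc_curve <- function(scores, truth, criterion = c("youden", "closest_topleft")) {
  criterion <- match.arg(criterion)
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- truth == "positive"
  if (!any(pos) || all(pos)) stop("evaluation error: both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(pos); nneg <- sum(!pos)
  # positive iff score >= threshold; prepend a threshold above all scores
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & pos) / npos, numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & !pos) / nneg, numeric(1)))
  thresholds <- c(Inf, thr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- switch(criterion,
              youden = tpr - fpr,
              closest_topleft = -(fpr^2 + (1 - tpr)^2))
  best <- which(j >= max(j) - 1e-12)
  cand <- thresholds[best]
  optimal <- if (any(is.finite(cand))) min(cand[is.finite(cand)]) else Inf
  out <- list(curve = data.frame(threshold = thresholds, fpr = fpr, tpr = tpr),
              auc = auc, optimal_threshold = optimal, criterion = criterion)
  class(out) <- "roc_curve"
  out
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f, optimal threshold %.4g (%s), %d points\n",
              x$auc, x$optimal_threshold, x$criterion, nrow(x$curve)))
  invisible(x)
}

#' Decision-curve analysis
#'
#' Net benefit of a model across threshold probabilities:
#' `NB(p_t) = TP/n - FP/n * p_t / (1 - p_t)`. With numeric scores the model
#' calls positive at `score >= p_t`; with fixed labels the counts are
#' constant across the grid. Treat-all and treat-none reference curves are
#' included (treat-none is identically 0).
#'
#' @param scores_or_labels Numeric scores in `[0, 1]` or character labels.
#' @param truth True labels.
#' @param thresholds Grid of threshold probabilities, strictly inside (0, 1).
#' @return Object of class `dca_curve`: data frame with `threshold`,
#'   `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(scores_or_labels, truth,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("threshold probabilities must lie strictly inside (0, 1)")
  }
  n <- length(truth)
  pos <- truth == "positive"
  fixed <- is.character(scores_or_labels) || is.factor(scores_or_labels)
  nb <- vapply(thresholds, function(pt) {
    called <- if (fixed) as.character(scores_or_labels) == "positive"
              else scores_or_labels >= pt
    tp <- sum(called & pos); fp <- sum(called & !pos)
    tp / n - fp / n * pt / (1 - pt)
  }, numeric(1))
  treat_all <- vapply(thresholds, function(pt) {
    sum(pos) / n - sum(!pos) / n * pt / (1 - pt)
  }, numeric(1))
  out <- list(curve = data.frame(threshold = thresholds, net_benefit = nb,
                                 treat_all = treat_all, treat_none = 0))
  class(out) <- "dca_curve"
  out
}

#' Logistic-regression baseline
#'
#' Maximum-likelihood logistic regression of the biopsy outcome on the six
#' classifier input variables; the comparator statistical model. Scores are
#' predicted probabilities; the decision threshold is taken from the training
#' ROC ([roc_curve()]).
#'
#' @param train Labeled cohort.
#' @param variables Predictors (default: the six classifier inputs).
#' @return Object of class `lr_baseline`: the `glm` fit, the training
#'   [roc_curve()], and `threshold`.
#' @export
fit_lr_baseline <- function(train, variables = fis_variables()) {
  dat <- train[train$label %in% c("negative", "positive"), , drop = FALSE]
  dat$y <- as.integer(dat$label == "positive")
  for (v in intersect(variables, names(.cat_levels))) {
    dat[[v]] <- factor(dat[[v]], levels = .cat_levels[[v]])
  }
  form <- stats::as.formula(paste("y ~", paste(variables, collapse = " + ")))
  fit <- stats::glm(form, data = dat, family = stats::binomial())
  if (!fit$converged) warning("logistic regression did not converge")
  scores <- stats::predict(fit, type = "response")
  roc <- roc_curve(scores, dat$label)
  out <- list(fit = fit, roc = roc, threshold = roc$optimal_threshold,
              variables = variables)
  class(out) <- "lr_baseline"
  out
}

#' Predict with the logistic baseline
#'
#' @param object An `lr_baseline`.
#' @param newdata Cohort data frame.
#' @param type `"score"` for predicted probabilities, `"label"` for classes
#'   at the training-ROC threshold.
#' @param ... Unused.
#' @export
predict.lr_baseline <- function(object, newdata, type = c("score", "label"), ...) {
  type <- match.arg(type)
  dat <- as.data.frame(newdata, stringsAsFactors = FALSE)
  for (v in intersect(object$variables, names(.cat_levels))) {
    dat[[v]] <- factor(dat[[v]], levels = .cat_levels[[v]])
  }
  p <- stats::predict(object$fit, newdata = dat, type = "response")
  if (type == "score") unname(p)
  else ifelse(p >= object$threshold, "positive", "negative")
}

#' Univariate threshold baselines
#'
#' The standard diagnostic comparators: a patient is called positive when the
#' chosen variable is equal to or greater than the threshold (e.g. PSA 3.45
#' ng/mL, PSA density 0.10 ng/mL^2, PI-RADS 4 — the training-ROC optima of
#' the development cohort).
#'
#' @param cohort Cohort data frame.
#' @param variable One of `"psa"`, `"psa_density"`, `"pirads"`.
#' @param threshold Decision threshold.
#' @return Character vector of labels.
#' @export
univariate_baseline <- function(cohort, variable = c("psa", "psa_density", "pirads"),
                                threshold) {
  variable <- match.arg(variable)
  x <- cohort[[variable]]
  if (is.null(x) || anyNA(x)) stop("missing value(s) in variable: ", variable)
  ifelse(x >= threshold, "positive", "negative")
}

#' Evaluate the cascade against all comparator models
#'
#' Runs the full comparison: the fitted cascade, logistic regression on the
#' same six variables, and the three univariate baselines. Baseline
#' thresholds are the training-ROC optima (Youden); the cascade decides with
#' its own stages. Metrics are computed on both the training and the
#' evaluation cohort.
#'
#' @param model A fitted `fb_cascade`.
#' @param train Labeled training cohort (models and thresholds come from it).
#' @param test Labeled evaluation cohort.
#' @return Object of class `fb_evaluation`: `metrics` (data frame, one row
#'   per model per set with counts and percentage metrics), `auc` (training
#'   AUCs), `thresholds`, and the per-model score vectors.
#' @export
evaluate_models <- function(model, train, test) {
  lr <- fit_lr_baseline(train)
  sets <- list(training = train, validation = test)
  uni_vars <- c(psa = "psa", psa_density = "psa_density", pirads = "pirads")

  # training-ROC optimal thresholds for the univariate tools
  thresholds <- vapply(uni_vars, function(v) {
    roc_curve(train[[v]], train$label)$optimal_threshold
  }, numeric(1))

  model_scores <- function(cohort) {
    list(
      fis_svm = predict(model, cohort)$score,
      lr = predict(lr, cohort, type = "score"),
      psa = cohort$psa,
      psa_density = cohort$psa_density,
      pirads = cohort$pirads
    )
  }
  model_labels <- function(cohort) {
    list(
      fis_svm = predict(model, cohort)$label,
      lr = predict(lr, cohort, type = "label"),
      psa = univariate_baseline(cohort, "psa", thresholds[["psa"]]),
      psa_density = univariate_baseline(cohort, "psa_density",
                                        thresholds[["psa_density"]]),
      pirads = univariate_baseline(cohort, "pirads", thresholds[["pirads"]])
    )
  }

  rows <- list()
  scores <- list()
  for (set in names(sets)) {
    cohort <- sets[[set]]
    labs <- model_labels(cohort)
    scores[[set]] <- model_scores(cohort)
    for (m in names(labs)) {
      met <- metrics_from_counts(confusion_counts(labs[[m]], cohort$label))
      rows[[length(rows) + 1L]] <- data.frame(
        set = set, model = m,
        tp = met$counts$tp, tn = met$counts$tn,
        fp = met$counts$fp, fn = met$counts$fn,
        npv = met$pct[["npv"]], ppv = met$pct[["ppv"]],
        specificity = met$pct[["specificity"]],
        sensitivity = met$pct[["sensitivity"]],
        accuracy = met$pct[["accuracy"]],
        stringsAsFactors = FALSE
      )
    }
  }
  auc <- vapply(names(scores$training), function(m) {
    roc_curve(scores$training[[m]], train$label)$auc
  }, numeric(1))
  out <- list(metrics = do.call(rbind, rows), auc = auc,
              thresholds = c(fis_svm = model$fis_threshold,
                             lr = lr$threshold, thresholds),
              scores = scores)
  class(out) <- "fb_evaluation"
  out
}

#' @export
print.fb_evaluation <- function(x, ...) {
  cat("Model comparison (percentages rounded half-up to 1 decimal):\n")
  print(x$metrics, row.names = FALSE)
  cat("\nTraining AUCs:\n")
  print(round(x$auc, 3))
  invisible(x)
}

#' Reference confusion counts of the development study
#'
#' The published operating points of the five models (fuzzy cascade, logistic
#' regression, PSA, PSA density, PI-RADS) on the development and validation
#' cohorts of the clinical study this classifier family was developed on,
#' shipped as a plain-text fixture. Used to check that the metric formulas
#' reproduce every published derived value.
#'
#' @return Data frame with columns `set`, `model`, `tp`, `tn`, `fp`, `fn` and
#'   the published percentage metrics.
#' @export
reference_confusion_counts <- function() {
  path <- system.file("extdata", "reference_confusion_counts.csv",
                      package = "fuzzybiopsy", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
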