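# The end-to-end classifier: fuzzy inference first; patients matched by no
# rule are classified by a linear-kernel SVM trained on the whole training
# set over the same six encoded variables.

#' Linear kernel
#'
#' The inner product `t(x) %*% y` used by the SVM stage.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar kernel value.
#' @export
linear_kernel <- function(x, y) sum(x * y)

#' Fit the fuzzy-rule / SVM cascade
#'
#' Trains the full personalized predictive model on a labeled cohort:
#' a fuzzy rule base is induced by [induce_rule_base()] (per-class SOM
#' clustering, FP-growth mining, predominance filtering), and a linear-kernel
#' support vector machine is fitted on the *entire* training set with the
#' same six input variables (one-hot / min-max encoded). At prediction time
#' the fuzzy system classifies every patient it can; the SVM classifies the
#' rest, so coverage is always 100%.
#'
#' @param train Labeled training cohort (both classes present).
#' @param fis_cfg A [fis_config()].
#' @param som_cfg A [som_config()]; its seed drives all stochastic steps.
#' @param scheme Binarization scheme (default aligned with the membership
#'   functions).
#' @param min_support,predominance_threshold Rule-induction parameters.
#' @param svm_cost SVM regularization parameter C.
#' @return An object of class `fb_cascade` with the rule base, the frozen
#'   feature encoder, the separator weights/bias, and training summaries.
#' @examples
#' \donttest{
#' coh <- generate_synthetic_cohort(cohort_spec(n = 300, seed = 2))
#' fit <- fit_cascade(coh)
#' print(fit)
#' head(predict(fit, coh))
#' }
#' @export
fit_cascade <- function(train, fis_cfg = fis_config(), som_cfg = som_config(),
                        scheme = default_binarization(fis_cfg$variables),
                        min_support = 0.25, predominance_threshold = 3,
                        svm_cost = 1) {
  labeled <- train[train$label %in% c("negative", "positive"), , drop = FALSE]
  core <- labeled[, fis_variables(), drop = FALSE]
  ok <- !apply(is.na(core), 1L, any)
  labeled <- labeled[ok, , drop = FALSE]
  if (length(unique(labeled$label)) < 2L) {
    stop("training error: both outcome classes must be present")
  }
  rulebase <- induce_rule_base(labeled, som_cfg = som_cfg, fis_cfg = fis_cfg,
                               scheme = scheme, min_support = min_support,
                               predominance_threshold = predominance_threshold)
  encoder <- make_encoder(labeled)
  x <- encode_features(labeled, encoder)
  y <- factor(labeled$label, levels = c("negative", "positive"))
  svmfit <- e1071::svm(x, y, kernel = "linear", cost = svm_cost,
                       scale = FALSE)
  w <- drop(t(svmfit$coefs) %*% svmfit$SV)
  b <- -svmfit$rho
  # orient the separator so that margin > 0 means the positive class, then
  # check the frozen weights reproduce the fitted SVM's own predictions
  theirs <- as.character(stats::predict(svmfit, x))
  own <- ifelse(drop(x %*% w) + b >= 0, "positive", "negative")
  if (mean(own == theirs) < 0.5) {
    w <- -w; b <- -b
    own <- ifelse(drop(x %*% w) + b >= 0, "positive", "negative")
  }
  if (mean(own == theirs) < 0.999) {
    stop("internal error: extracted separator disagrees with the fitted SVM")
  }

  model <- structure(list(
    rulebase = rulebase,
    fis_threshold = fis_cfg$threshold,
    encoder = encoder,
    svm = list(weights = w, bias = b, cost = svm_cost),
    seed = som_cfg$seed,
    n_train = nrow(labeled),
    version = 1L
  ), class = "fb_cascade")
  tr_pred <- predict(model, labeled)
  model$training <- list(
    n_fis = sum(tr_pred$stage == "fis"),
    n_svm = sum(tr_pred$stage == "svm"),
    accuracy = mean(tr_pred$label == labeled$label)
  )
  model
}

# squash an SVM margin into [0, 1] so cascade scores share one scale with the
# defuzzified FIS score (monotone, 0.5 at the decision boundary)
.squash_margin <- function(m) 1 / (1 + exp(-m))

#' Predict biopsy outcomes with the cascade
#'
#' Every patient first goes through the fuzzy inference system; patients
#' matched by at least one rule get its defuzzified decision (`stage =
#' "fis"`), the rest are classified by the linear SVM (`stage = "svm"`,
#' positive when the signed margin is >= 0). Coverage is 100% by
#' construction. The `score` column places both stages on `[0, 1]`: the
#' defuzzified score where the FIS classified, the logistic-squashed margin
#' where the SVM did (the cascade itself returns no probability; this
#' monotone score exists for ROC sweeps).
#'
#' @param object A fitted `fb_cascade`.
#' @param newdata Cohort data frame with the six input variables.
#' @param ... Unused.
#' @return Data frame with one row per patient: `patient_id`, `label`,
#'   `stage`, `score`, `fis_status`, `svm_margin`, `n_matched_rules`.
#' @export
predict.fb_cascade <- function(object, newdata, ...) {
  cohort <- as.data.frame(newdata, stringsAsFactors = FALSE)
  fis <- .fis_scores(object$rulebase, cohort, object$fis_threshold)
  x <- encode_features(cohort, object$encoder)
  margin <- drop(x %*% object$svm$weights) + object$svm$bias
  svm_label <- ifelse(margin >= 0, "positive", "negative")
  nc <- fis$status == "not_classified"
  acts <- .rule_activations(object$rulebase, cohort)
  data.frame(
    patient_id = if ("patient_id" %in% names(cohort)) cohort$patient_id
                 else sprintf("row%d", seq_len(nrow(cohort))),
    label = ifelse(nc, svm_label, fis$label),
    stage = ifelse(nc, "svm", "fis"),
    score = ifelse(nc, .squash_margin(margin), fis$score),
    fis_status = fis$status,
    svm_margin = margin,
    n_matched_rules = rowSums(acts > 0),
    stringsAsFactors = FALSE
  )
}

#' @export
print.fb_cascade <- function(x, ...) {
  cons <- vapply(x$rulebase$rules, `[[`, character(1), "consequent")
  cat("Fuzzy-rule / SVM cascade classifier\n")
  cat(sprintf("  rule base: %d rules (%d negative, %d positive)\n",
              length(cons), sum(cons == "negative"), sum(cons == "positive")))
  cat(sprintf("  trained on %d patients; FIS classified %d (%.1f%%), SVM %d\n",
              x$n_train, x$training$n_fis,
              100 * x$training$n_fis / x$n_train, x$training$n_svm))
  cat(sprintf("  FIS threshold %.2f; SVM linear kernel, C = %g\n",
              x$fis_threshold, x$svm$cost))
  invisible(x)
}

#' @export
summary.fb_cascade <- function(object, ...) {
  print(object)
  cat(sprintf("  training accuracy: %.3f\n", object$training$accuracy))
  cat("  rules:\n")
  cat(paste0("   ", format_rules(object$rulebase)), sep = "\n")
  invisible(object)
}

#' @export
coef.fb_cascade <- function(object, ...) {
  c(object$svm$weights, bias = object$svm$bias)
}

#' ROC curve plot for a fitted cascade
#'
#' Plots the training-cohort ROC of the cascade score (defuzzified FIS score
#' where classified, squashed SVM margin elsewhere).
#'
#' @param x A fitted `fb_cascade`.
#' @param cohort Labeled cohort to evaluate (for example the training set).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fb_cascade <- function(x, cohort, ...) {
  pred <- predict(x, cohort)
  roc <- roc_curve(pred$score, cohort$label)
  graphics::plot(roc$curve$fpr, roc$curve$tpr, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("Cascade ROC (AUC %.3f)", roc$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(roc)
}

#' Save / load a fitted cascade as JSON
#'
#' The whole model (rule base, encoder statistics, separator weights, seeds)
#' is stored in a single human-readable JSON document with a version field;
#' a reloaded model predicts identically to the in-memory one.
#'
#' @param model A fitted `fb_cascade`.
#' @param path File path.
#' @return `write_cascade` returns `path` invisibly; `read_cascade` the model.
#' @export
write_cascade <- function(model, path) {
  stopifnot(inherits(model, "fb_cascade"))
  enc <- model$encoder
  doc <- list(
    format = "fb_cascade", version = model$version,
    rulebase = .rulebase_to_list(model$rulebase),
    fis_threshold = model$fis_threshold,
    encoder = list(variables = enc$variables, numeric = enc$numeric,
                   categorical = enc$categorical,
                   mins = as.list(stats::setNames(.num_out(enc$mins), names(enc$mins))),
                   maxs = as.list(stats::setNames(.num_out(enc$maxs), names(enc$maxs))),
                   levels = enc$levels, dims = enc$dims),
    svm = list(weights = as.list(stats::setNames(.num_out(model$svm$weights),
                                                 names(model$svm$weights))),
               bias = .num_out(model$svm$bias), cost = model$svm$cost),
    seed = model$seed, n_train = model$n_train, training = model$training
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cascade
#' @export
read_cascade <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "fb_cascade")) stop("not a cascade model file: ", path)
  enc <- list(variables = unlist(doc$encoder$variables),
              numeric = unlist(doc$encoder$numeric),
              categorical = unlist(doc$encoder$categorical),
              mins = vapply(doc$encoder$mins, .num_in, numeric(1)),
              maxs = vapply(doc$encoder$maxs, .num_in, numeric(1)),
              levels = lapply(doc$encoder$levels, unlist),
              dims = unlist(doc$encoder$dims))
  class(enc) <- "fb_encoder"
  model <- structure(list(
    rulebase = .rulebase_from_list(doc$rulebase),
    fis_threshold = as.numeric(doc$fis_threshold),
    encoder = enc,
    svm = list(weights = vapply(doc$svm$weights, .num_in, numeric(1)),
               bias = .num_in(doc$svm$bias), cost = as.numeric(doc$svm$cost)),
    seed = as.integer(doc$seed),
    n_train = as.integer(doc$n_train),
    training = lapply(doc$training, function(v) unlist(v)),
    version = as.integer(doc$version)
  ), class = "fb_cascade")
  model
}
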