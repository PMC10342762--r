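# Mamdani inference over the induced rule base: min for AND, max aggregation
# per consequent class, centroid defuzzification of the clipped output sets.

# activation matrix: one row per record, one column per rule; activation is
# the minimum of the antecedent term degrees
.rule_activations <- function(rulebase, cohort) {
  n <- nrow(cohort)
  acts <- matrix(0, n, length(rulebase$rules),
                 dimnames = list(NULL, vapply(rulebase$rules, `[[`,
                                              character(1), "id")))
  for (j in seq_along(rulebase$rules)) {
    r <- rulebase$rules[[j]]
    a <- rep(1, n)
    for (v in names(r$antecedent)) {
      vdef <- rulebase$variables[[v]]
      a <- pmin(a, .term_degree(vdef, r$antecedent[[v]], cohort[[v]]))
    }
    acts[, j] <- a
  }
  acts
}

# vectorized inference over a cohort; returns one row per record
.fis_scores <- function(rulebase, cohort, threshold = rulebase$threshold) {
  if (length(rulebase$rules) == 0L) stop("empty rule base")
  for (v in fis_variables()) {
    if (!v %in% names(cohort)) stop("record(s) missing variable: ", v)
    if (anyNA(cohort[[v]])) stop("missing value(s) in variable: ", v)
  }
  acts <- .rule_activations(rulebase, cohort)
  cons <- vapply(rulebase$rules, `[[`, character(1), "consequent")
  a_neg <- if (any(cons == "negative")) {
    do.call(pmax, c(as.data.frame(acts[, cons == "negative", drop = FALSE]), 0))
  } else rep(0, nrow(cohort))
  a_pos <- if (any(cons == "positive")) {
    do.call(pmax, c(as.data.frame(acts[, cons == "positive", drop = FALSE]), 0))
  } else rep(0, nrow(cohort))

  g <- seq(0, 1, length.out = rulebase$grid_points)
  w <- rep(1, length(g)); w[c(1, length(g))] <- 0.5 # trapezoid weights
  mu_neg <- membership_degree(rulebase$output$negative, g)
  mu_pos <- membership_degree(rulebase$output$positive, g)
  # clipped-and-aggregated output set, evaluated on the grid for each record
  clip_neg <- outer(a_neg, mu_neg, pmin)
  clip_pos <- outer(a_pos, mu_pos, pmin)
  agg <- pmax(clip_neg, clip_pos)
  mass <- as.vector(agg %*% w)
  score <- as.vector(agg %*% (w * g)) / ifelse(mass > 0, mass, 1)

  classified <- (a_neg + a_pos) > 0
  data.frame(
    status = ifelse(classified, "classified", "not_classified"),
    score = ifelse(classified, score, NA_real_),
    label = ifelse(classified,
                   ifelse(score >= threshold, "positive", "negative"),
                   NA_character_),
    activation_negative = a_neg,
    activation_positive = a_pos,
    stringsAsFactors = FALSE
  )
}

#' Fuzzy inference for one patient
#'
#' Runs the Mamdani inference: each rule's activation is the minimum of its
#' antecedent membership degrees; activations are aggregated per consequent
#' class by maximum; the two output membership functions are clipped at their
#' class activation, combined by maximum, and defuzzified by centroid to a
#' crisp score in `[0, 1]`. The patient is labeled positive when the score
#' reaches the threshold. If no rule fires at all, the status is
#' `not_classified` (NC) and the patient is left for the cascade's SVM stage.
#'
#' @param rulebase A `fuzzy_rulebase` from [induce_rule_base()].
#' @param record Single-row data frame with the six input variables.
#' @param threshold Decision threshold on the score (default: the rule base's
#'   configured threshold, 0.5).
#' @return An object of class `fis_result`: `status`
#'   (`classified`/`not_classified`), `score`, `label`, and `matched_rules`
#'   (data frame of rule id, activation, consequent for every rule with
#'   activation > 0).
#' @export
fis_infer <- function(rulebase, record, threshold = rulebase$threshold) {
  stopifnot(inherits(rulebase, "fuzzy_rulebase"))
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  if (nrow(record) != 1L) stop("fis_infer classifies one record; see predict() for cohorts")
  res <- .fis_scores(rulebase, record, threshold)
  acts <- .rule_activations(rulebase, record)[1L, ]
  fired <- which(acts > 0)
  out <- list(
    status = res$status[1L],
    score = res$score[1L],
    label = res$label[1L],
    matched_rules = data.frame(
      rule_id = names(acts)[fired],
      activation = unname(acts[fired]),
      consequent = vapply(rulebase$rules[fired], `[[`, character(1),
                          "consequent"),
      stringsAsFactors = FALSE
    )
  )
  class(out) <- "fis_result"
  out
}

#' @export
print.fis_result <- function(x, ...) {
  if (x$status == "not_classified") {
    cat("FIS result: not classified (no rule matched)\n")
  } else {
    cat(sprintf("FIS result: %s (score %.3f, %d rule(s) matched)\n",
                x$label, x$score, nrow(x$matched_rules)))
  }
  invisible(x)
}

#' Explain a fuzzy inference result
#'
#' Renders the rules that matched a patient as human-readable IF-THEN lines
#' with their activation degrees; a not-classified result states that no rule
#' matched and the decision was deferred to the SVM stage.
#'
#' @param result A `fis_result` from [fis_infer()].
#' @param rulebase The rule base that produced it.
#' @return Character vector of explanation lines.
#' @export
explain <- function(result, rulebase) {
  stopifnot(inherits(result, "fis_result"), inherits(rulebase, "fuzzy_rulebase"))
  if (result$status == "not_classified") {
    return("no rule matched; deferred to SVM stage")
  }
  ids <- vapply(rulebase$rules, `[[`, character(1), "id")
  lines <- character(nrow(result$matched_rules))
  for (i in seq_len(nrow(result$matched_rules))) {
    j <- match(result$matched_rules$rule_id[i], ids)
    if (is.na(j)) stop("rule id not in rule base: ", result$matched_rules$rule_id[i])
    r <- rulebase$rules[[j]]
    ante <- paste(sprintf("%s IS %s", names(r$antecedent), r$antecedent),
                  collapse = " AND ")
    lines[i] <- sprintf("IF %s THEN %s (activation %.2f)", ante, r$consequent,
                        result$matched_rules$activation[i])
  }
  lines
}
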