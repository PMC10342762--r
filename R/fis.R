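# Fuzzy inference: membership functions, the default fuzzy variables over the
# six classifier inputs, Mamdani inference (min AND, max aggregation, centroid
# defuzzification) and the not-classified outcome.

#' Triangular and trapezoidal membership functions
#'
#' Piecewise-linear membership functions. `triangular(a, b, c)` rises from 0
#' at `a` to 1 at `b` and falls back to 0 at `c`; `trapezoidal(a, b, c, d)`
#' has plateau `[b, c]` at degree 1. Infinite `a` (or `d`) gives an open left
#' (right) shoulder with degree 1 below `b` (above `c`). Parameters must be
#' non-decreasing.
#'
#' @param a,b,c,d Breakpoints (non-decreasing; `-Inf`/`Inf` allowed at the
#'   outer ends).
#' @param label Linguistic term name.
#' @return An object of class `membership_function`.
#' @export
triangular <- function(a, b, c, label = "term") {
  trapezoidal(a, b, b, c, label = label)
}

#' @rdname triangular
#' @export
trapezoidal <- function(a, b, c, d, label = "term") {
  p <- c(a, b, c, d)
  dp <- diff(p) # -Inf,-Inf or Inf,Inf neighbours give NaN: equal, so fine
  if (any(dp[!is.nan(dp)] < 0)) {
    stop("membership-function parameters must be non-decreasing")
  }
  mf <- list(shape = if (b == c) "triangular" else "trapezoidal",
             a = a, b = b, c = c, d = d, label = label)
  class(mf) <- "membership_function"
  mf
}

#' Degree of membership
#'
#' Evaluates a piecewise-linear membership function: 0 outside the support,
#' 1 on the peak or plateau, linear on the edges.
#'
#' @param mf A [triangular()] or [trapezoidal()] membership function.
#' @param x Numeric value(s); must be finite.
#' @return Degree(s) in `[0, 1]`.
#' @examples
#' membership_degree(triangular(0, 1, 2), 1) # 1
#' membership_degree(trapezoidal(0, 1, 2, 3), 2.5) # 0.5
#' @export
membership_degree <- function(mf, x) {
  stopifnot(inherits(mf, "membership_function"))
  if (any(!is.finite(x))) stop("membership_degree requires finite x")
  up <- if (is.infinite(mf$a)) rep(1, length(x)) else {
    ifelse(x <= mf$a, 0, ifelse(x >= mf$b, 1,
                                (x - mf$a) / max(mf$b - mf$a, .Machine$double.eps)))
  }
  down <- if (is.infinite(mf$d)) rep(1, length(x)) else {
    ifelse(x >= mf$d, 0, ifelse(x <= mf$c, 1,
                                (mf$d - x) / max(mf$d - mf$c, .Machine$double.eps)))
  }
  pmin(up, down)
}

#' Default fuzzy variables for the six classifier inputs
#'
#' The shipped fuzzification of the six prebiopsy inputs. PSA density gets
#' low/medium/high terms crossing at 0.10 and 0.15 ng/mL^2 (the clinical
#' cut-offs commonly used for biopsy decisions); lesion count gets
#' one/two/three-plus terms; PI-RADS scores and the three categorical
#' variables are crisp terms (degree 0/1). These parameters are modelling
#' assumptions and can be replaced wholesale by passing a modified list to
#' [fis_config()].
#'
#' @return Named list of fuzzy variable definitions. Numeric variables have
#'   `type = "numeric"` and a list of membership functions; categorical ones
#'   have `type = "categorical"` and their levels as crisp terms.
#' @export
default_fuzzy_variables <- function() {
  list(
    psa_density = list(type = "numeric", terms = list(
      trapezoidal(-Inf, 0, 0.075, 0.125, label = "low"),
      triangular(0.075, 0.125, 0.175, label = "medium"),
      trapezoidal(0.125, 0.175, Inf, Inf, label = "high")
    )),
    dre = list(type = "categorical", terms = c("negative", "positive")),
    prior_biopsy = list(type = "categorical", terms = c("no", "yes")),
    n_lesions = list(type = "numeric", terms = list(
      trapezoidal(-Inf, -Inf, 1, 2, label = "one"),
      triangular(1, 2, 3, label = "two"),
      trapezoidal(2, 3, Inf, Inf, label = "three_plus")
    )),
    lesion_location = list(type = "categorical",
                           terms = c("peripheral", "transitional_anterior")),
    pirads = list(type = "categorical_numeric", terms = c("3", "4", "5"))
  )
}

#' Fuzzy-inference configuration
#'
#' Bundles the fuzzy variable definitions, the two output membership
#' functions (negative peaking at 0, positive peaking at 1, crossing at 0.5)
#' and the decision threshold on the defuzzified score.
#'
#' @param variables Fuzzy variable definitions, as
#'   [default_fuzzy_variables()].
#' @param threshold Crisp decision threshold on the defuzzified score in
#'   `[0, 1]`; scores at or above it are positive.
#' @param grid_points Number of points for numeric centroid defuzzification
#'   over `[0, 1]` (trapezoid rule).
#' @return An object of class `fis_config`.
#' @export
fis_config <- function(variables = default_fuzzy_variables(), threshold = 0.5,
                       grid_points = 201L) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  cfg <- list(variables = variables, threshold = threshold,
              output = list(negative = triangular(-Inf, 0, 1, label = "negative"),
                            positive = triangular(0, 1, Inf, label = "positive")),
              grid_points = as.integer(grid_points))
  class(cfg) <- "fis_config"
  cfg
}

# term labels of a fuzzy variable
.term_labels <- function(vdef) {
  if (vdef$type == "numeric") {
    vapply(vdef$terms, function(t) t$label, character(1))
  } else {
    as.character(vdef$terms)
  }
}

# degree of a record's value in one (variable, term); vectorised over values
.term_degree <- function(vdef, term, values) {
  if (vdef$type == "numeric") {
    labels <- .term_labels(vdef)
    mf <- vdef$terms[[match(term, labels)]]
    membership_degree(mf, values)
  } else {
    as.numeric(as.character(values) == term)
  }
}

#' Default binarization scheme
#'
#' Derives the interval binarization used before FP-growth mining from the
#' fuzzy variable definitions, so mined itemsets translate directly to fuzzy
#' antecedents: each numeric variable is split at the crossing points of
#' adjacent membership functions (half-open intervals, one per term) and each
#' categorical level becomes one binary item.
#'
#' @param variables Fuzzy variable definitions, as
#'   [default_fuzzy_variables()].
#' @return Object of class `binarization_scheme`: per variable, the term
#'   labels and, for numeric variables, the interval break points.
#' @export
default_binarization <- function(variables = default_fuzzy_variables()) {
  scheme <- list()
  for (v in names(variables)) {
    vdef <- variables[[v]]
    labels <- .term_labels(vdef)
    if (vdef$type == "numeric") {
      # crossing of term i's falling edge and term i+1's rising edge:
      # midpoint of [c_i, d_i] overlap with [a_{i+1}, b_{i+1}]
      breaks <- numeric(length(vdef$terms) - 1L)
      for (i in seq_along(breaks)) {
        lo <- vdef$terms[[i]]$c
        hi <- vdef$terms[[i]]$d
        lo2 <- vdef$terms[[i + 1L]]$a
        hi2 <- vdef$terms[[i + 1L]]$b
        breaks[i] <- (max(lo, lo2) + min(hi, hi2)) / 2
      }
      scheme[[v]] <- list(type = "numeric", terms = labels,
                          breaks = c(-Inf, breaks, Inf))
    } else {
      scheme[[v]] <- list(type = "categorical", terms = labels)
    }
  }
  class(scheme) <- "binarization_scheme"
  scheme
}

#' Binarize a cohort into a transaction matrix
#'
#' Maps every record to exactly one binary item per variable: for numeric
#' variables the half-open interval `[break_i, break_{i+1})` containing the
#' value, named after the matching fuzzy term; for categorical variables the
#' matching level. Column order is deterministic (scheme order).
#'
#' @param cohort Cohort data frame.
#' @param scheme A [default_binarization()] scheme.
#' @return Binary matrix, rows = patients, columns named `"variable=term"`.
#' @export
binarize <- function(cohort, scheme = default_binarization()) {
  stopifnot(inherits(scheme, "binarization_scheme"))
  n <- nrow(cohort)
  cols <- character(0)
  for (v in names(scheme)) {
    cols <- c(cols, paste(v, scheme[[v]]$terms, sep = "="))
  }
  m <- matrix(0L, n, length(cols), dimnames = list(cohort$patient_id, cols))
  for (v in names(scheme)) {
    s <- scheme[[v]]
    vals <- cohort[[v]]
    if (anyNA(vals)) stop("missing value(s) in variable '", v, "'")
    if (s$type == "numeric") {
      idx <- findInterval(vals, s$breaks, left.open = FALSE)
      # findInterval with -Inf/Inf sentinels returns 1..(#terms)
      if (any(idx < 1L | idx > length(s$terms))) {
        stop("scheme-coverage error: variable '", v, "' has value outside all intervals")
      }
    } else {
      idx <- match(as.character(vals), s$terms)
      if (anyNA(idx)) {
        bad <- as.character(vals)[which(is.na(idx))[1]]
        stop("scheme-coverage error: variable '", v, "' value '", bad,
             "' matches no category")
      }
    }
    m[cbind(seq_len(n), match(paste(v, s$terms[idx], sep = "="), cols))] <- 1L
  }
  m
}
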