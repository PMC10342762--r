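# Gower-distance KNN and exhaustive feature-subset search.

# variables treated as numeric in the Gower distance (pirads and n_lesions are
# ordinal and kept numeric to preserve their ordering)
.gower_numeric <- c("age", "psa", "psa_density", "n_lesions", "pirads",
                    "prostate_volume", "lesion_volume")
.gower_categorical <- c("dre", "prior_biopsy", "lesion_location")

#' Numeric ranges for the Gower distance
#'
#' Computes the per-variable min-max ranges of a training cohort, used to
#' normalise numeric contributions to the Gower distance. Ranges are frozen at
#' training and reused at prediction time.
#'
#' @param cohort Training cohort data frame.
#' @param variables Variables to cover (default: all Gower-numeric variables
#'   present).
#' @return Named numeric vector of ranges (max - min).
#' @export
gower_ranges <- function(cohort, variables = NULL) {
  if (is.null(variables)) variables <- intersect(.gower_numeric, names(cohort))
  num <- intersect(variables, .gower_numeric)
  r <- vapply(num, function(v) {
    x <- cohort[[v]]
    diff(range(x, na.rm = TRUE))
  }, numeric(1))
  r
}

#' Gower distance between two patient records
#'
#' Mixed-type dissimilarity: the unweighted mean over the chosen variables of
#' `|a - b| / range` for numeric variables and a 0/1 mismatch indicator for
#' categorical ones. Lies in `[0, 1]`, is symmetric, and is 0 exactly when the
#' two records agree on every chosen variable.
#'
#' @param a,b Single-row data frames (or list-like records) holding the
#'   variables.
#' @param variables Character vector of variable names to compare.
#' @param ranges Named numeric vector of ranges for the numeric variables
#'   (strictly positive).
#' @return Distance in `[0, 1]`.
#' @examples
#' r <- c(psa_density = 0.4)
#' a <- list(psa_density = 0.10); b <- list(psa_density = 0.30)
#' gower_distance(a, b, "psa_density", r) # 0.5
#' @export
gower_distance <- function(a, b, variables, ranges) {
  d <- 0
  for (v in variables) {
    av <- a[[v]]; bv <- b[[v]]
    if (is.null(av) || is.null(bv) || is.na(av) || is.na(bv)) {
      stop("both records must have variable '", v, "'")
    }
    if (v %in% .gower_categorical || is.character(av)) {
      d <- d + as.numeric(av != bv)
    } else {
      rv <- ranges[[v]]
      if (is.null(rv) || is.na(rv) || rv <= 0) {
        stop("range for numeric variable '", v, "' must be strictly positive")
      }
      d <- d + abs(av - bv) / rv
    }
  }
  d / length(variables)
}

# per-variable dissimilarity matrices between rows of `query` and rows of
# `train` (list of |variables| matrices); the Gower distance for any subset is
# the mean of the corresponding slices
.gower_parts <- function(query, train, variables, ranges) {
  parts <- vector("list", length(variables))
  names(parts) <- variables
  for (v in variables) {
    qx <- query[[v]]; tx <- train[[v]]
    if (v %in% .gower_categorical || is.character(qx)) {
      parts[[v]] <- outer(qx, tx, FUN = "!=") * 1
    } else {
      rv <- ranges[[v]]
      if (is.null(rv) || is.na(rv) || rv <= 0) {
        stop("range for numeric variable '", v, "' must be strictly positive")
      }
      parts[[v]] <- abs(outer(qx, tx, FUN = "-")) / rv
    }
  }
  parts
}

# majority vote among the k nearest (all records tied with the k-th distance
# are included); label ties resolve to "negative"
.knn_vote <- function(dists, labels, k) {
  ord <- order(dists)
  kth <- dists[ord[k]]
  nb <- labels[dists <= kth + 1e-12]
  npos <- sum(nb == "positive")
  nneg <- length(nb) - npos
  if (npos > nneg) "positive" else "negative"
}

#' KNN classification with the Gower distance
#'
#' Assigns a query record the majority label among its k nearest training
#' records under the Gower distance. Records tied with the k-th neighbour
#' distance are all included in the vote; a tied vote resolves to
#' `"negative"` (the clinically conservative default when ruling biopsies
#' out). Both conventions make the result invariant to the ordering of the
#' training records.
#'
#' @param query Single-row data frame (or record) to classify.
#' @param train Labeled training cohort.
#' @param k Number of neighbours (default 33, the development setting).
#' @param variables Variables entering the distance (default: the six
#'   classifier inputs).
#' @param ranges Numeric ranges for Gower normalisation; computed from
#'   `train` when omitted.
#' @return `"negative"` or `"positive"`.
#' @export
knn_classify <- function(query, train, k = 33, variables = fis_variables(),
                         ranges = NULL) {
  if (k <= 0 || k > nrow(train)) stop("k must be in 1..nrow(train)")
  if (any(!train$label %in% c("negative", "positive"))) {
    stop("all training records must be labeled negative/positive")
  }
  if (is.null(ranges)) ranges <- gower_ranges(train, variables)
  qdf <- as.data.frame(query, stringsAsFactors = FALSE)
  parts <- .gower_parts(qdf, train, variables, ranges)
  d <- Reduce(`+`, parts)[1, ] / length(variables)
  .knn_vote(d, train$label, k)
}

# stratified fold assignment (per-class round robin after a seeded shuffle)
.stratified_folds <- function(labels, nfolds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

#' Exhaustive feature-subset search with a Gower-KNN scorer
#'
#' Enumerates every non-empty subset of the candidate variables and scores
#' each as input to a k-nearest-neighbour classifier with the Gower distance,
#' by stratified cross-validated accuracy. Results are returned best-first;
#' ties break toward smaller subsets and then lexicographically.
#'
#' @param train Labeled cohort.
#' @param candidates Candidate variable names (at most 15).
#' @param k Number of neighbours (default 33).
#' @param nfolds Cross-validation folds (default 5).
#' @param seed Seed controlling fold assignment.
#' @return Data frame with columns `subset` (comma-joined variable names),
#'   `size`, `score` (CV accuracy), and `evaluation_scheme`.
#' @export
exhaustive_subset_search <- function(train, candidates, k = 33, nfolds = 5,
                                     seed = 1L) {
  if (length(candidates) > 15L) stop("at most 15 candidate variables (2^p - 1 subsets)")
  if (any(!train$label %in% c("negative", "positive"))) {
    stop("unlabeled records present; label every record negative/positive")
  }
  n <- nrow(train)
  if (k > n) stop("k must not exceed the cohort size")
  ranges <- gower_ranges(train, candidates)
  parts <- .gower_parts(train, train, candidates, ranges)
  fold <- .stratified_folds(train$label, nfolds, seed)
  labels <- train$label

  p <- length(candidates)
  subsets <- lapply(seq_len(2^p - 1L), function(m) candidates[bitwAnd(m, 2^(seq_len(p) - 1L)) > 0])
  score_subset <- function(vars) {
    D <- Reduce(`+`, parts[vars]) / length(vars)
    correct <- 0L
    for (f in seq_len(nfolds)) {
      te <- which(fold == f); tr <- which(fold != f)
      kk <- min(k, length(tr))
      for (i in te) {
        pred <- .knn_vote(D[i, tr], labels[tr], kk)
        if (pred == labels[i]) correct <- correct + 1L
      }
    }
    correct / n
  }
  scores <- vapply(subsets, score_subset, numeric(1))
  subset_str <- vapply(subsets, function(s) paste(sort(s), collapse = ","), character(1))
  res <- data.frame(subset = subset_str,
                    size = lengths(subsets),
                    score = scores,
                    evaluation_scheme = sprintf("cv%d-accuracy", nfolds),
                    stringsAsFactors = FALSE)
  res[order(-res$score, res$size, res$subset), , drop = FALSE]
}
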