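# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (brute force / enumeration) and share no code with the
# implementation paths they check.

# random patient-like records for distance property tests
random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("R%04d", seq_len(n)),
    age = runif(n, 45, 85),
    psa = runif(n, 0.5, 40),
    psa_density = runif(n, 0.02, 0.5),
    dre = sample(c("negative", "positive"), n, replace = TRUE),
    prior_biopsy = sample(c("no", "yes"), n, replace = TRUE),
    n_lesions = sample(1:3, n, replace = TRUE),
    lesion_location = sample(c("peripheral", "transitional_anterior"), n,
                             replace = TRUE, prob = c(0.85, 0.15)),
    pirads = sample(3:5, n, replace = TRUE),
    label = sample(c("negative", "positive"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# cohort whose label is exactly determined by psa_density and pirads
# (positive iff psa_density >= 0.10 and pirads >= 4); the other four inputs
# are constant so they carry no class information
separable_cohort <- function(n = 600, seed = 101) {
  set.seed(seed)
  psad <- runif(n, 0.02, 0.18)
  pirads <- sample(3:5, n, replace = TRUE)
  lab <- ifelse(psad >= 0.10 & pirads >= 4, "positive", "negative")
  data.frame(
    patient_id = sprintf("S%04d", seq_len(n)),
    age = 68, psa = psad * 50, psa_density = psad,
    dre = "negative", prior_biopsy = "no",
    n_lesions = 1L, lesion_location = "peripheral", pirads = pirads,
    prostate_volume = 50, lesion_volume = 1,
    label = lab, stringsAsFactors = FALSE
  )
}

# cohort spec with strong class-conditional signal on all six inputs
strong_signal_spec <- function(n, seed) {
  cohort_spec(
    n = n, prevalence = 0.5, seed = seed,
    psa_density = list(mean = 0.17, sd = 0.06, delta = 0.18),
    dre_pos = list(neg = 0.02, pos = 0.75),
    prior_biopsy_yes = list(neg = 0.55, pos = 0.05),
    pirads_probs = list(neg = c(0.85, 0.14, 0.01), pos = c(0.02, 0.23, 0.75)),
    n_lesions_probs = list(neg = c(0.90, 0.08, 0.02), pos = c(0.35, 0.40, 0.25))
  )
}

# brute-force frequent-itemset enumeration over all 2^p - 1 candidate sets
enumerate_itemsets <- function(m, min_support) {
  m <- as.matrix(m) > 0
  items <- colnames(m)
  n <- nrow(m)
  out <- list()
  for (size in seq_along(items)) {
    combos <- utils::combn(items, size, simplify = FALSE)
    for (s in combos) {
      cnt <- sum(rowSums(m[, s, drop = FALSE]) == length(s))
      if (cnt >= min_support * n - 1e-9 && cnt > 0) {
        out[[length(out) + 1L]] <- data.frame(
          itemset = paste(sort(s), collapse = ","), count = cnt,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(itemset = character(0), count = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(-res$count, res$itemset), , drop = FALSE]
}

# brute-force KNN using the scalar pairwise distance only
brute_knn <- function(query, train, k, variables, ranges) {
  d <- vapply(seq_len(nrow(train)), function(i) {
    gower_distance(query, train[i, , drop = FALSE], variables, ranges)
  }, numeric(1))
  kth <- sort(d)[k]
  nb <- train$label[d <= kth + 1e-12]
  if (sum(nb == "positive") > sum(nb == "negative")) "positive" else "negative"
}

# AUC as the normalized Mann-Whitney U statistic (ties counted 1/2)
mann_whitney_auc <- function(scores, truth) {
  pos <- scores[truth == "positive"]
  neg <- scores[truth == "negative"]
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# random transaction matrices for mining equivalence tests
random_transactions <- function(n_trans, n_items, seed, p = 0.4) {
  set.seed(seed)
  m <- matrix(rbinom(n_trans * n_items, 1, p), n_trans, n_items)
  colnames(m) <- LETTERS[seq_len(n_items)]
  m
}
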