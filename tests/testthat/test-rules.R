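test_that("binarization sets exactly one item per variable", {
  scheme <- default_binarization()
  coh <- random_records(40, seed = 3)
  m <- binarize(coh, scheme)
  expect_true(all(rowSums(m) == length(fis_variables())))
  # one active item within each variable block
  for (v in fis_variables()) {
    block <- m[, startsWith(colnames(m), paste0(v, "=")), drop = FALSE]
    expect_true(all(rowSums(block) == 1))
  }
})

test_that("binarization places boundary values in the upper interval", {
  scheme <- default_binarization()
  rec <- random_records(3, seed = 4)
  rec$psa_density <- c(0.05, 0.12, 0.15)
  m <- binarize(rec, scheme)
  expect_equal(unname(m[, "psa_density=low"]), c(1, 0, 0))
  expect_equal(unname(m[, "psa_density=medium"]), c(0, 1, 0))
  expect_equal(unname(m[, "psa_density=high"]), c(0, 0, 1))
  rec$dre <- c("positive", "negative", "negative")
  m2 <- binarize(rec, scheme)
  expect_equal(unname(m2[, "dre=positive"]), c(1, 0, 0))
  expect_equal(unname(m2[, "dre=negative"]), c(0, 1, 1))
  # out-of-scheme categorical value is a coverage error
  rec$dre[1] <- "equivocal"
  expect_error(binarize(rec, scheme), "coverage")
})

test_that("predominance filtering keeps one-class rules only", {
  m <- cbind("dre=positive" = c(rep(1, 10), rep(0, 10)))
  # pure rule: 10 negative matches, 0 positive -> kept, consequent negative
  lab_pure <- c(rep("negative", 10), rep("positive", 10))
  sc <- score_predominance("dre=positive", m, lab_pure, threshold = 2)
  expect_true(sc$kept)
  expect_identical(sc$consequent, "negative")
  expect_equal(sc$n_match_neg, 10)
  expect_equal(sc$n_match_pos, 0)
  expect_equal(sc$predominance, 10) # pure: majority / max(1, 0)
  # 5 vs 5 matches: no predominance, discarded under any threshold > 1
  lab_even <- c(rep(c("negative", "positive"), 5), rep("negative", 10))
  sc2 <- score_predominance("dre=positive", m, lab_even, threshold = 1.01)
  expect_false(sc2$kept)
  expect_equal(sc2$predominance, 1)
  # unmatched antecedent (max count 0) is never kept
  m0 <- cbind("dre=positive" = rep(0, 4))
  sc3 <- score_predominance("dre=positive", m0,
                            rep(c("negative", "positive"), 2), threshold = 1)
  expect_false(sc3$kept)
})

test_that("rule induction is deterministic and structurally sound", {
  coh <- generate_synthetic_cohort(cohort_spec(n = 300, seed = 31))
  rb1 <- induce_rule_base(coh, som_cfg = som_config(epochs = 10, seed = 2))
  rb2 <- induce_rule_base(coh, som_cfg = som_config(epochs = 10, seed = 2))
  expect_identical(rb1, rb2)
  expect_gt(length(rb1$rules), 0)

  m <- binarize(coh, rb1$scheme)
  for (r in rb1$rules) {
    # recount oracle: stored counts equal a direct tally over the cohort
    items <- paste(names(r$antecedent), r$antecedent, sep = "=")
    match_row <- rowSums(m[, items, drop = FALSE]) == length(items)
    expect_equal(r$n_match_pos, sum(match_row & coh$label == "positive"))
    expect_equal(r$n_match_neg, sum(match_row & coh$label == "negative"))
    expect_gte(r$predominance, rb1$predominance_threshold)
    # consequent consistent with the larger count
    expect_identical(r$consequent,
                     if (r$n_match_pos > r$n_match_neg) "positive" else "negative")
    # at most one term per variable
    expect_false(anyDuplicated(names(r$antecedent)) > 0)
  }
})

test_that("kept antecedents are frequent itemsets of their source cluster", {
  coh <- generate_synthetic_cohort(cohort_spec(n = 200, seed = 37))
  som_cfg <- som_config(epochs = 10, seed = 5)
  rb <- induce_rule_base(coh, som_cfg = som_cfg, min_support = 0.3)
  m <- binarize(coh, rb$scheme)
  # rebuild the per-class clusterings exactly as induction does
  enc <- make_encoder(coh)
  clusters <- list()
  for (ci in 1:2) {
    cls <- c("negative", "positive")[ci]
    rows <- which(coh$label == cls)
    cfg_c <- som_cfg
    cfg_c$seed <- som_cfg$seed + (ci - 1L)
    g <- train_som(encode_features(coh[rows, ], enc), cfg_c)
    cl <- assign_clusters(g, encode_features(coh[rows, ], enc))
    for (neuron in unique(cl)) {
      clusters[[sprintf("%s/cluster%02d", cls, neuron)]] <- rows[cl == neuron]
    }
  }
  for (r in rb$rules) {
    items <- paste(names(r$antecedent), r$antecedent, sep = "=")
    ok <- vapply(r$provenance, function(pv) {
      rows <- clusters[[pv]]
      sub <- m[rows, , drop = FALSE]
      supp <- mean(rowSums(sub[, items, drop = FALSE]) == length(items))
      supp >= 0.3 - 1e-9
    }, logical(1))
    expect_true(all(ok), info = r$id)
  }
})

test_that("a separable cohort yields only pure rules", {
  coh <- separable_cohort(n = 600, seed = 101)
  rb <- induce_rule_base(coh, som_cfg = som_config(epochs = 15, seed = 1))
  expect_gt(length(rb$rules), 0)
  for (r in rb$rules) {
    expect_equal(min(r$n_match_pos, r$n_match_neg), 0, info = r$id)
  }
})

test_that("rule base JSON round-trips", {
  coh <- generate_synthetic_cohort(cohort_spec(n = 150, seed = 41))
  rb <- induce_rule_base(coh, som_cfg = som_config(epochs = 5, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_rulebase(rb, path)
  back <- read_rulebase(path)
  expect_equal(back, rb)
})
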