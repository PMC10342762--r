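test_that("membership degrees follow the piecewise-linear definition", {
  tri <- triangular(0, 1, 2)
  expect_equal(membership_degree(tri, 1), 1)
  expect_equal(membership_degree(tri, 0), 0)
  expect_equal(membership_degree(tri, 2), 0)
  expect_equal(membership_degree(tri, 0.5), 0.5)
  trap <- trapezoidal(0, 1, 2, 3)
  expect_equal(membership_degree(trap, 2.5), 0.5)
  expect_equal(membership_degree(trap, 1.5), 1)
  expect_equal(membership_degree(trap, -1), 0)
  # open shoulders: degree 1 beyond the plateau
  lsh <- trapezoidal(-Inf, -Inf, 1, 2)
  expect_equal(membership_degree(lsh, -100), 1)
  expect_equal(membership_degree(lsh, 1.5), 0.5)
  rsh <- trapezoidal(2, 3, Inf, Inf)
  expect_equal(membership_degree(rsh, 100), 1)
  expect_error(membership_degree(tri, NA_real_), "finite")
  expect_error(triangular(2, 1, 0), "non-decreasing")
})

test_that("default fuzzy variables cover their domains", {
  vars <- default_fuzzy_variables()
  for (x in c(0, 0.05, 0.10, 0.1234, 0.15, 0.4, 3)) {
    degs <- vapply(vars$psa_density$terms,
                   function(mf) membership_degree(mf, x), numeric(1))
    expect_gt(sum(degs), 0)
    expect_equal(max(degs) <= 1, TRUE)
  }
  # crossings at the clinical cut-offs 0.10 and 0.15
  d10 <- vapply(vars$psa_density$terms,
                function(mf) membership_degree(mf, 0.10), numeric(1))
  expect_equal(unname(d10[1:2]), c(0.5, 0.5))
  d15 <- vapply(vars$psa_density$terms,
                function(mf) membership_degree(mf, 0.15), numeric(1))
  expect_equal(unname(d15[2:3]), c(0.5, 0.5))
})

# a minimal hand-built rule base: one rule per class on crisp dre
mini_rulebase <- function(threshold = 0.5) {
  coh <- random_records(60, seed = 77)
  coh$label <- ifelse(coh$dre == "positive", "positive", "negative")
  suppressWarnings(
    induce_rule_base(coh, som_cfg = som_config(epochs = 5, seed = 1),
                     min_support = 0.9, predominance_threshold = 2,
                     fis_cfg = fis_config(threshold = threshold))
  )
}

test_that("single firing positive rule defuzzifies to the triangle centroid", {
  rb <- mini_rulebase()
  # keep only one positive-consequent crisp rule: IF dre IS positive THEN positive
  keep <- vapply(rb$rules, function(r) {
    identical(names(r$antecedent), "dre") && r$consequent == "positive"
  }, logical(1))
  expect_true(any(keep))
  rb$rules <- rb$rules[keep][1]
  rec <- random_records(1, seed = 5)
  rec$dre <- "positive"
  res <- fis_infer(rb, rec)
  # clipped positive output at activation 1 is mu(x) = x on [0,1]:
  # centroid = (1/3) / (1/2) = 2/3
  expect_equal(res$score, 2 / 3, tolerance = 1e-4)
  expect_identical(res$label, "positive")
  expect_identical(res$status, "classified")
  expect_identical(res$matched_rules$rule_id, rb$rules[[1]]$id)
  # no rule fires -> not classified
  rec$dre <- "negative"
  res_nc <- fis_infer(rb, rec)
  expect_identical(res_nc$status, "not_classified")
  expect_equal(nrow(res_nc$matched_rules), 0L)
})

test_that("score is monotone in positive-rule activation and bounded", {
  rb <- mini_rulebase()
  set.seed(12)
  g <- seq(0, 1, length.out = rb$grid_points)
  w <- rep(1, length(g)); w[c(1, length(g))] <- 0.5
  centroid <- function(a_neg, a_pos) {
    mu <- pmax(pmin(a_neg, 1 - g), pmin(a_pos, g))
    if (sum(mu) == 0) return(NA_real_)
    sum(mu * g * w) / sum(mu * w)
  }
  for (rep in 1:100) {
    a_neg <- runif(1)
    a_pos <- sort(runif(2))
    s1 <- centroid(a_neg, a_pos[1])
    s2 <- centroid(a_neg, a_pos[2])
    expect_gte(s2, s1 - 1e-12)
    expect_gte(s1, 0); expect_lte(s1, 1)
    # only one side firing lands on the right side of 0.5
    expect_lt(centroid(runif(1, 0.1, 1), 0), 0.5)
    expect_gt(centroid(0, runif(1, 0.1, 1)), 0.5)
  }
})

test_that("inference splits any cohort into classified + not-classified", {
  coh <- generate_synthetic_cohort(cohort_spec(n = 200, seed = 19))
  rb <- induce_rule_base(coh, som_cfg = som_config(epochs = 10, seed = 2))
  statuses <- vapply(seq_len(50), function(i) {
    fis_infer(rb, coh[i, ])$status
  }, character(1))
  expect_true(all(statuses %in% c("classified", "not_classified")))
  expect_error(fis_infer(rb, coh[1:2, ]), "one record")
  rb0 <- rb; rb0$rules <- list()
  expect_error(fis_infer(rb0, coh[1, ]), "empty rule base")
})

test_that("explanations render matched rules exactly", {
  coh <- generate_synthetic_cohort(cohort_spec(n = 200, seed = 23))
  rb <- induce_rule_base(coh, som_cfg = som_config(epochs = 10, seed = 2))
  found <- FALSE
  for (i in 1:50) {
    res <- fis_infer(rb, coh[i, ])
    if (res$status == "classified") {
      found <- TRUE
      lines <- explain(res, rb)
      expect_length(lines, nrow(res$matched_rules))
      expect_true(all(grepl("^IF .+ THEN (negative|positive) \\(activation", lines)))
    } else {
      expect_match(explain(res, rb), "no rule matched")
    }
  }
  expect_true(found)
})
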