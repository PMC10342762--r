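test_that("cohort CSV round-trips losslessly", {
  coh <- generate_synthetic_cohort(cohort_spec(n = 50, seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_identical(back$patient_id, coh$patient_id)
  for (v in c("dre", "prior_biopsy", "lesion_location", "label")) {
    expect_identical(back[[v]], coh[[v]])
  }
  for (v in c("age", "psa", "psa_density", "n_lesions", "pirads",
              "prostate_volume", "lesion_volume")) {
    expect_identical(back[[v]], as.numeric(coh[[v]]))
  }
})

test_that("empty and single-record cohorts write header-first CSVs", {
  coh <- generate_synthetic_cohort(cohort_spec(n = 1, seed = 1))
  empty <- coh[0, , drop = FALSE]
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(empty, p1)
  write_cohort_csv(coh, p2)
  expect_length(readLines(p1), 1L)
  expect_length(readLines(p2), 2L)
})

test_that("reader rejects out-of-domain values with the offending row", {
  coh <- generate_synthetic_cohort(cohort_spec(n = 5, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  coh$pirads[3] <- 6
  write.csv(coh, path, row.names = FALSE)
  expect_error(read_cohort_csv(path), "row.*3")
  coh$pirads[3] <- 4
  coh$dre[2] <- "maybe"
  write.csv(coh, path, row.names = FALSE)
  expect_error(read_cohort_csv(path), "dre")
})

test_that("reader maps schema columns and normalises categorical case", {
  coh <- generate_synthetic_cohort(cohort_spec(n = 5, seed = 3))
  names(coh)[names(coh) == "psa_density"] <- "PSAdens"
  coh$dre <- toupper(coh$dre)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(coh, path, row.names = FALSE)
  expect_error(read_cohort_csv(path), "psa_density")
  back <- read_cohort_csv(path, schema = c(psa_density = "PSAdens"))
  expect_true(all(back$dre %in% c("negative", "positive")))
})

test_that("generator is deterministic and hits the requested prevalence", {
  spec <- cohort_spec(n = 1448, prevalence = 0.569, seed = 11)
  a <- generate_synthetic_cohort(spec)
  b <- generate_synthetic_cohort(spec)
  expect_identical(a, b)
  # binomial 99% CI around 0.569 at n = 1448
  phat <- mean(a$label == "positive")
  half <- 2.576 * sqrt(0.569 * (1 - 0.569) / 1448)
  expect_gt(phat, 0.569 - half)
  expect_lt(phat, 0.569 + half)
  expect_error(cohort_spec(prevalence = 1.2), "prevalence")
})

test_that("class-conditional mean shift is recovered from the sample", {
  delta <- 0.08
  spec <- cohort_spec(n = 5000, seed = 13,
                      psa_density = list(mean = 0.17, sd = 0.17, delta = delta))
  coh <- generate_synthetic_cohort(spec)
  pos <- coh$psa_density[coh$label == "positive"]
  neg <- coh$psa_density[coh$label == "negative"]
  diff_hat <- mean(pos) - mean(neg)
  se <- sqrt(var(pos) / length(pos) + var(neg) / length(neg))
  expect_lt(abs(diff_hat - delta), 3 * se)
})

test_that("marginal moments match the cohort spec as n grows", {
  coh <- generate_synthetic_cohort(cohort_spec(n = 10000, seed = 17))
  # age: marginal mean 69, sd 8
  expect_lt(abs(mean(coh$age) - 69), 3 * 8 / sqrt(10000))
  # PI-RADS marginal distribution ~ 27.9 / 56.6 / 15.5 % at default prevalence
  p4 <- mean(coh$pirads == 4)
  expect_lt(abs(p4 - 0.566), 3 * sqrt(0.566 * 0.434 / 10000) + 0.01)
  # positive DRE marginal ~ 12%
  expect_lt(abs(mean(coh$dre == "positive") - 0.12), 0.02)
  # PSA consistent with density * volume by construction
  expect_equal(coh$psa, coh$psa_density * coh$prostate_volume)
})

test_that("validation flags ineligible and inconsistent records", {
  coh <- generate_synthetic_cohort(cohort_spec(n = 10, seed = 5))
  coh$psa_density[4] <- NA
  expect_warning(v <- validate_cohort(coh), "ineligible")
  expect_identical(attr(v, "ineligible_rows"), 4L)
  coh2 <- generate_synthetic_cohort(cohort_spec(n = 10, seed = 5))
  coh2$psa_density[2] <- coh2$psa_density[2] * 2
  expect_error(validate_cohort(coh2), "inconsistent")
  coh3 <- generate_synthetic_cohort(cohort_spec(n = 10, seed = 5))
  coh3$patient_id[2] <- coh3$patient_id[1]
  expect_error(validate_cohort(coh3), "unique")
})
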