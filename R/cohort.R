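# Domain types, validation, CSV I/O and the synthetic-cohort generator.

#' Prebiopsy variables used by the fuzzy inference system
#'
#' The six prebiopsy variables the classifier operates on: PSA density,
#' digital rectal examination, previous fusion biopsy, number of suspicious
#' lesions at mpMRI, lesion location, and PI-RADS score.
#'
#' @return Character vector of canonical column names.
#' @export
fis_variables <- function() {
  c("psa_density", "dre", "prior_biopsy", "n_lesions", "lesion_location", "pirads")
}

# canonical categorical levels; first level is the reference/"absent" state
.cat_levels <- list(
  dre             = c("negative", "positive"),
  prior_biopsy    = c("no", "yes"),
  lesion_location = c("peripheral", "transitional_anterior"),
  label           = c("negative", "positive", "unknown")
)

.numeric_vars <- c("age", "psa", "psa_density", "n_lesions", "pirads",
                   "prostate_volume", "lesion_volume")

.required_cols <- c("patient_id", "age", "psa", "psa_density", "dre",
                    "prior_biopsy", "n_lesions", "lesion_location", "pirads")

.optional_cols <- c("prostate_volume", "lesion_volume", "label")

#' Validate a patient cohort
#'
#' Checks a cohort data frame against the domain constraints: unique patient
#' ids, non-negative PSA and PSA density, at least one lesion, PI-RADS score
#' in 3-5, recognised categorical levels, and (when both are present)
#' consistency of PSA density with PSA / prostate volume. Records missing any
#' of the six classifier input variables are reported as ineligible for
#' training/prediction but are not dropped.
#'
#' @param cohort Data frame with one row per patient (see [read_cohort_csv()]
#'   for the column contract).
#' @param psa_density_tol Relative tolerance for the PSA-density consistency
#'   check against `psa / prostate_volume`.
#' @return The validated cohort (invisibly unchanged) with an
#'   `ineligible_rows` attribute listing row indices lacking a classifier
#'   input variable.
#' @export
validate_cohort <- function(cohort, psa_density_tol = 0.05) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(.required_cols, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(cohort) > 0L) {
    if (anyDuplicated(cohort$patient_id)) {
      stop("patient_id values must be unique within a cohort")
    }
    bad <- function(cond, what) {
      idx <- which(cond)
      if (length(idx) > 0L) {
        stop("validation error (", what, ") at row(s): ",
             paste(utils::head(idx, 10L), collapse = ", "))
      }
    }
    bad(!is.na(cohort$psa) & cohort$psa < 0, "psa < 0")
    bad(!is.na(cohort$psa_density) & cohort$psa_density < 0, "psa_density < 0")
    bad(!is.na(cohort$n_lesions) & cohort$n_lesions < 1, "n_lesions < 1")
    bad(!is.na(cohort$pirads) & !(cohort$pirads %in% 3:5), "pirads not in {3,4,5}")
    for (v in c("dre", "prior_biopsy", "lesion_location")) {
      bad(!is.na(cohort[[v]]) & !(cohort[[v]] %in% .cat_levels[[v]]),
          paste0(v, " not in {", paste(.cat_levels[[v]], collapse = ","), "}"))
    }
    if ("label" %in% names(cohort)) {
      bad(!is.na(cohort$label) & !(cohort$label %in% .cat_levels$label),
          "label not in {negative,positive,unknown}")
    }
    if ("prostate_volume" %in% names(cohort)) {
      both <- !is.na(cohort$psa) & !is.na(cohort$prostate_volume) &
        !is.na(cohort$psa_density) & cohort$prostate_volume > 0
      implied <- cohort$psa[both] / cohort$prostate_volume[both]
      off <- abs(cohort$psa_density[both] - implied) >
        psa_density_tol * pmax(implied, 1e-8)
      if (any(off)) {
        stop("psa_density inconsistent with psa/prostate_volume at row(s): ",
             paste(utils::head(which(both)[off], 10L), collapse = ", "))
      }
    }
  }
  inel <- integer(0)
  if (nrow(cohort) > 0L) {
    core <- cohort[, fis_variables(), drop = FALSE]
    inel <- which(apply(is.na(core), 1L, any))
    if (length(inel) > 0L) {
      warning(length(inel), " record(s) lack a classifier input variable and are ",
              "ineligible for training/prediction (rows ",
              paste(utils::head(inel, 10L), collapse = ", "), ")")
    }
  }
  attr(cohort, "ineligible_rows") <- inel
  invisible(cohort)
}

#' Read a patient cohort from CSV
#'
#' Reads a comma-separated, UTF-8, header-first cohort file into a validated
#' data frame. Categorical strings are normalised case-insensitively to the
#' canonical levels (`dre`: negative/positive; `prior_biopsy`: no/yes;
#' `lesion_location`: peripheral/transitional_anterior; `label`:
#' negative/positive/unknown). A missing or empty `label` becomes `"unknown"`.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the column names used in the file, e.g.
#'   `c(psa_density = "PSAdens")`.
#' @return A validated cohort data frame.
#' @seealso [write_cohort_csv()], [validate_cohort()]
#' @export
read_cohort_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      user <- schema[[canon]]
      if (!user %in% names(raw)) stop("schema error: column '", user, "' not in file")
      names(raw)[names(raw) == user] <- canon
    }
  }
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  cohort <- raw[, intersect(c(.required_cols, .optional_cols), names(raw)), drop = FALSE]
  cohort$patient_id <- as.character(cohort$patient_id)
  for (v in intersect(.numeric_vars, names(cohort))) {
    x <- cohort[[v]]
    if (!is.numeric(x)) {
      xs <- trimws(as.character(x))
      xn <- suppressWarnings(as.numeric(xs))
      bad <- which(!is.na(xs) & nzchar(xs) & is.na(xn))
      if (length(bad) > 0L) {
        stop("unparseable numeric value for '", v, "' at row(s): ",
             paste(utils::head(bad, 10L), collapse = ", "))
      }
      x <- xn
    }
    cohort[[v]] <- as.numeric(x)
  }
  for (v in intersect(names(.cat_levels), names(cohort))) {
    x <- trimws(tolower(as.character(cohort[[v]])))
    x[is.na(x) | x == "" | x == "na"] <- NA_character_
    canon <- .cat_levels[[v]]
    m <- canon[match(x, tolower(canon))]
    bad <- which(!is.na(x) & is.na(m))
    if (length(bad) > 0L) {
      stop("validation error: out-of-domain '", v, "' value at row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "))
    }
    cohort[[v]] <- m
  }
  if (!"label" %in% names(cohort)) cohort$label <- "unknown"
  cohort$label[is.na(cohort$label)] <- "unknown"
  validate_cohort(cohort)
}

#' Write a patient cohort to CSV
#'
#' Writes the cohort so that [read_cohort_csv()] round-trips it exactly:
#' numeric columns are rendered with 17 significant digits.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort
  for (v in intersect(.numeric_vars, names(out))) {
    x <- out[[v]]
    s <- ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
    out[[v]] <- s
  }
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "",
                     fileEncoding = "UTF-8"),
    error = function(e) stop("cannot write cohort CSV to '", path, "': ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Specification of a synthetic patient cohort
#'
#' Collects the parameters of the synthetic-cohort generator. Defaults emulate
#' the development population of the classifier: n = 1448 patients with a
#' 56.9% positive-biopsy prevalence, right-skewed (log-normal) PSA density,
#' prostate and lesion volumes, a 12% positive-DRE rate, and a 27.9/56.6/15.5%
#' PI-RADS 3/4/5 distribution. Class-conditional structure follows the
#' variables that differ significantly between positive and negative biopsies
#' in that population (age, PSA density, DRE rate, prostate and lesion
#' volumes, PI-RADS distribution); the effect sizes are assumptions, exposed
#' here as parameters. For numeric variables the `delta` entry is the
#' difference in class means (positive minus negative); class means are placed
#' so the marginal mean is preserved at the given prevalence. PSA is derived
#' as `psa_density * prostate_volume` so the two are always consistent.
#'
#' @param n Number of patients.
#' @param prevalence Fraction with a positive biopsy outcome.
#' @param seed Integer seed; the same spec with the same seed generates an
#'   identical cohort.
#' @param age,psa_density,prostate_volume,lesion_volume Lists with `mean`,
#'   `sd` and class-mean difference `delta` (positive minus negative class).
#' @param dre_pos,prior_biopsy_yes Per-class probabilities (`neg`, `pos`) of a
#'   positive DRE / a previous biopsy.
#' @param n_lesions_probs Per-class probability vectors over 1, 2, 3 lesions.
#' @param lesion_transitional Per-class probabilities of a
#'   transitional/anterior lesion location.
#' @param pirads_probs Per-class probability vectors over PI-RADS 3, 4, 5.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 1448,
                        prevalence = 0.569,
                        seed = 1L,
                        age = list(mean = 69, sd = 8, delta = 3),
                        psa_density = list(mean = 0.17, sd = 0.17, delta = 0.07),
                        prostate_volume = list(mean = 55.8, sd = 27.8, delta = -13),
                        lesion_volume = list(mean = 0.98, sd = 1.91, delta = 0.5),
                        dre_pos = list(neg = 0.054, pos = 0.17),
                        prior_biopsy_yes = list(neg = 0.35, pos = 0.26),
                        n_lesions_probs = list(neg = c(0.75, 0.20, 0.05),
                                               pos = c(0.75, 0.20, 0.05)),
                        lesion_transitional = list(neg = 0.145, pos = 0.145),
                        pirads_probs = list(neg = c(0.41, 0.53, 0.06),
                                            pos = c(0.18, 0.59, 0.23))) {
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1) {
    stop("prevalence must be in [0, 1]")
  }
  if (n < 0) stop("n must be non-negative")
  for (p in list(dre_pos, prior_biopsy_yes, lesion_transitional)) {
    if (any(unlist(p) < 0 | unlist(p) > 1)) stop("probabilities must be in [0, 1]")
  }
  for (p in c(n_lesions_probs, pirads_probs)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("category probabilities must be non-negative and sum to 1")
    }
  }
  spec <- list(n = as.integer(n), prevalence = prevalence, seed = as.integer(seed),
               age = age, psa_density = psa_density,
               prostate_volume = prostate_volume, lesion_volume = lesion_volume,
               dre_pos = dre_pos, prior_biopsy_yes = prior_biopsy_yes,
               n_lesions_probs = n_lesions_probs,
               lesion_transitional = lesion_transitional,
               pirads_probs = pirads_probs)
  class(spec) <- "cohort_spec"
  spec
}

# class means preserving the marginal mean at the given prevalence
.class_means <- function(par, prevalence) {
  c(neg = par$mean - prevalence * par$delta,
    pos = par$mean + (1 - prevalence) * par$delta)
}

# log-normal draw with given arithmetic mean and sd
.rlnorm_ms <- function(n, m, s) {
  if (m <= 0) stop("log-normal mean must be positive")
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

#' Generate a synthetic patient cohort
#'
#' Draws a cohort of synthetic patients from a [cohort_spec()]. Labels are
#' Bernoulli at the specified prevalence; numeric variables are drawn per class
#' (normal age, log-normal PSA density and volumes, identical class SDs) and
#' categorical variables from per-class probabilities. PSA is computed as
#' PSA density times prostate volume. Identical spec and seed give an
#' identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A validated cohort data frame with a `label` column.
#' @examples
#' coh <- generate_synthetic_cohort(cohort_spec(n = 100, seed = 7))
#' table(coh$label)
#' @export
generate_synthetic_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  lab <- ifelse(stats::runif(n) < spec$prevalence, "positive", "negative")
  pos <- lab == "positive"
  pick <- function(par) ifelse(pos, par[["pos"]], par[["neg"]])

  age_m <- .class_means(spec$age, spec$prevalence)
  age <- stats::rnorm(n, mean = ifelse(pos, age_m["pos"], age_m["neg"]),
                      sd = spec$age$sd)
  age <- pmax(age, 40)

  draw_lnorm <- function(par) {
    m <- .class_means(par, spec$prevalence)
    out <- numeric(n)
    if (any(!pos)) out[!pos] <- .rlnorm_ms(sum(!pos), m["neg"], par$sd)
    if (any(pos))  out[pos]  <- .rlnorm_ms(sum(pos), m["pos"], par$sd)
    out
  }
  psad <- draw_lnorm(spec$psa_density)
  pvol <- draw_lnorm(spec$prostate_volume)
  lvol <- draw_lnorm(spec$lesion_volume)
  psa <- psad * pvol

  dre <- ifelse(stats::runif(n) < pick(spec$dre_pos), "positive", "negative")
  pbx <- ifelse(stats::runif(n) < pick(spec$prior_biopsy_yes), "yes", "no")
  loc <- ifelse(stats::runif(n) < pick(spec$lesion_transitional),
                "transitional_anterior", "peripheral")

  draw_cat <- function(probs, values) {
    out <- integer(n)
    for (cls in c("neg", "pos")) {
      idx <- if (cls == "pos") which(pos) else which(!pos)
      if (length(idx) > 0L) {
        out[idx] <- sample(values, length(idx), replace = TRUE, prob = probs[[cls]])
      }
    }
    out
  }
  nles <- draw_cat(spec$n_lesions_probs, 1:3)
  pirads <- draw_cat(spec$pirads_probs, 3:5)

  cohort <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = age, psa = psa, psa_density = psad,
    dre = dre, prior_biopsy = pbx, n_lesions = nles,
    lesion_location = loc, pirads = pirads,
    prostate_volume = pvol, lesion_volume = lvol,
    label = lab,
    stringsAsFactors = FALSE
  )
  validate_cohort(cohort)
  cohort
}
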