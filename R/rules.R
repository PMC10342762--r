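# Automatic rule extraction: per-class SOM clustering, FP-growth mining of
# the interval-binarized clusters, and class-predominance filtering into a
# fuzzy rule base.

# parse "variable=term" item strings into a named character vector
# (variable -> term), ordered as in the scheme
.parse_antecedent <- function(items, scheme_order) {
  parts <- strsplit(items, "=", fixed = TRUE)
  vars <- vapply(parts, `[`, character(1), 1L)
  terms <- vapply(parts, function(p) paste(p[-1L], collapse = "="), character(1))
  o <- order(match(vars, scheme_order))
  stats::setNames(terms[o], vars[o])
}

#' Score a candidate rule's class predominance
#'
#' Counts, over the full training cohort, the patients of each class whose
#' binarized record satisfies the antecedent, and computes the predominance
#' ratio `max(n_pos, n_neg) / max(1, min(n_pos, n_neg))`. The rule is kept
#' when the predominance reaches the threshold and at least one patient
#' matches; its consequent is the majority class (a pure rule has infinite
#' predominance under the `max(1, .)` convention only when the minority count
#' is 0, in which case the ratio equals the majority count).
#'
#' @param antecedent Character vector of `"variable=term"` items.
#' @param transactions Binarized training cohort ([binarize()]).
#' @param labels Training labels aligned with `transactions` rows.
#' @param threshold Minimum predominance ratio to keep a rule.
#' @return List with `n_match_pos`, `n_match_neg`, `predominance`,
#'   `consequent`, and `kept`.
#' @export
score_predominance <- function(antecedent, transactions, labels, threshold = 3) {
  if (!all(antecedent %in% colnames(transactions))) {
    stop("antecedent item(s) not in transaction matrix: ",
         paste(setdiff(antecedent, colnames(transactions)), collapse = ", "))
  }
  match_row <- rowSums(transactions[, antecedent, drop = FALSE]) == length(antecedent)
  n_pos <- sum(match_row & labels == "positive")
  n_neg <- sum(match_row & labels == "negative")
  hi <- max(n_pos, n_neg); lo <- min(n_pos, n_neg)
  predominance <- hi / max(1, lo)
  list(n_match_pos = n_pos, n_match_neg = n_neg, predominance = predominance,
       consequent = if (n_pos > n_neg) "positive" else "negative",
       kept = hi > 0 && predominance >= threshold)
}

#' Induce a fuzzy rule base from a labeled cohort
#'
#' The four-step automatic rule-extraction procedure. For each outcome class:
#' (1) a 4x4 self-organizing map clusters the class's patients into
#' homogeneous subgroups; (2) each subgroup's records are binarized into one
#' interval/category item per variable; (3) FP-growth mines the subgroup's
#' frequent itemsets, each a candidate IF-THEN antecedent; (4) every
#' candidate's match counts are recounted on the full training cohort (both
#' classes) and only rules with a clear class predominance are kept, with the
#' majority class as consequent. Duplicate antecedents from different
#' clusters are merged (counts on the full cohort are identical); provenance
#' records every (class, cluster) source. Fully reproducible given the seed.
#'
#' @param train Labeled cohort (both classes present); records missing a
#'   classifier input are excluded with a warning.
#' @param som_cfg A [som_config()]; per-class maps use `seed` and `seed + 1`.
#' @param fis_cfg A [fis_config()] providing the fuzzy variables whose terms
#'   name the mined items.
#' @param scheme Binarization scheme; defaults to intervals aligned with the
#'   membership-function crossings ([default_binarization()]).
#' @param min_support Within-cluster minimum support for FP-growth.
#' @param predominance_threshold Minimum class-predominance ratio.
#' @return An object of class `fuzzy_rulebase`.
#' @export
induce_rule_base <- function(train, som_cfg = som_config(),
                             fis_cfg = fis_config(),
                             scheme = default_binarization(fis_cfg$variables),
                             min_support = 0.25,
                             predominance_threshold = 3) {
  labeled <- train[train$label %in% c("negative", "positive"), , drop = FALSE]
  core <- labeled[, fis_variables(), drop = FALSE]
  ok <- !apply(is.na(core), 1L, any)
  if (!all(ok)) {
    warning(sum(!ok), " record(s) missing a classifier input excluded from induction")
    labeled <- labeled[ok, , drop = FALSE]
  }
  classes <- c("negative", "positive")
  if (!all(classes %in% labeled$label)) {
    stop("both outcome classes must be present in the training cohort")
  }
  encoder <- make_encoder(labeled)
  transactions <- binarize(labeled, scheme)
  labels <- labeled$label

  candidates <- list() # antecedent string -> character vector of provenances
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    rows <- which(labels == cls)
    x <- encode_features(labeled[rows, , drop = FALSE], encoder)
    cfg_c <- som_cfg
    cfg_c$seed <- som_cfg$seed + (ci - 1L)
    grid <- train_som(x, cfg_c)
    cl <- assign_clusters(grid, x)
    for (neuron in sort(unique(cl))) {
      sub <- transactions[rows[cl == neuron], , drop = FALSE]
      fi <- fp_growth(sub, min_support)
      if (nrow(fi) == 0L) next
      prov <- sprintf("%s/cluster%02d", cls, neuron)
      for (s in fi$itemset) {
        candidates[[s]] <- c(candidates[[s]], prov)
      }
    }
  }

  rules <- list()
  for (s in names(candidates)) {
    items <- strsplit(s, ",", fixed = TRUE)[[1]]
    sc <- score_predominance(items, transactions, labels, predominance_threshold)
    if (!sc$kept) next
    rules[[length(rules) + 1L]] <- list(
      antecedent = .parse_antecedent(items, names(scheme)),
      consequent = sc$consequent,
      n_match_pos = sc$n_match_pos,
      n_match_neg = sc$n_match_neg,
      predominance = sc$predominance,
      provenance = sort(unique(candidates[[s]]))
    )
  }
  # deterministic order: negative-consequent rules first, then by antecedent
  key <- vapply(rules, function(r) {
    paste(r$consequent, paste(names(r$antecedent), r$antecedent,
                              sep = "=", collapse = ","))
  }, character(1))
  rules <- rules[order(key)]
  for (i in seq_along(rules)) rules[[i]]$id <- sprintf("R%03d", i)

  rb <- list(rules = rules, variables = fis_cfg$variables,
             output = fis_cfg$output, threshold = fis_cfg$threshold,
             grid_points = fis_cfg$grid_points, scheme = scheme,
             min_support = min_support,
             predominance_threshold = predominance_threshold,
             n_train = nrow(labeled))
  class(rb) <- "fuzzy_rulebase"
  rb
}

#' @export
print.fuzzy_rulebase <- function(x, ...) {
  cons <- vapply(x$rules, `[[`, character(1), "consequent")
  cat("Fuzzy rule base:", length(x$rules), "rules (",
      sum(cons == "negative"), "negative,", sum(cons == "positive"),
      "positive ) induced from", x$n_train, "patients\n")
  cat("min_support =", x$min_support, "; predominance threshold =",
      x$predominance_threshold, "\n")
  invisible(x)
}

#' Render a rule base as IF-THEN text
#'
#' @param rulebase A `fuzzy_rulebase`.
#' @return Character vector, one IF-THEN line per rule.
#' @export
format_rules <- function(rulebase) {
  vapply(rulebase$rules, function(r) {
    ante <- paste(sprintf("%s IS %s", names(r$antecedent), r$antecedent),
                  collapse = " AND ")
    sprintf("%s: IF %s THEN %s  [pos %d | neg %d, predominance %.2f]",
            r$id, ante, r$consequent, r$n_match_pos, r$n_match_neg,
            r$predominance)
  }, character(1))
}

# ---- serialization helpers (shared with the cascade model JSON) ----

# numeric parameters are stored as %.17g strings so that +/-Inf and full
# double precision survive the JSON round trip
.num_out <- function(x) sprintf("%.17g", x)
.num_in <- function(x) as.numeric(unlist(x))

.mf_to_list <- function(mf) {
  list(shape = mf$shape, a = .num_out(mf$a), b = .num_out(mf$b),
       c = .num_out(mf$c), d = .num_out(mf$d), label = mf$label)
}

.mf_from_list <- function(l) {
  trapezoidal(.num_in(l$a), .num_in(l$b), .num_in(l$c), .num_in(l$d),
              label = l$label)
}

.variables_to_list <- function(variables) {
  lapply(variables, function(vdef) {
    if (vdef$type == "numeric") {
      list(type = vdef$type, terms = lapply(vdef$terms, .mf_to_list))
    } else {
      list(type = vdef$type, terms = as.character(vdef$terms))
    }
  })
}

.variables_from_list <- function(l) {
  lapply(l, function(vdef) {
    if (vdef$type == "numeric") {
      list(type = vdef$type, terms = lapply(vdef$terms, .mf_from_list))
    } else {
      list(type = vdef$type, terms = unlist(vdef$terms))
    }
  })
}

.scheme_to_list <- function(scheme) {
  lapply(unclass(scheme), function(s) {
    out <- list(type = s$type, terms = s$terms)
    if (s$type == "numeric") out$breaks <- .num_out(s$breaks)
    out
  })
}

.scheme_from_list <- function(l) {
  scheme <- lapply(l, function(s) {
    out <- list(type = s$type, terms = unlist(s$terms))
    if (s$type == "numeric") out$breaks <- .num_in(s$breaks)
    out
  })
  class(scheme) <- "binarization_scheme"
  scheme
}

.rulebase_to_list <- function(rb) {
  list(
    rules = lapply(rb$rules, function(r) {
      list(id = r$id, antecedent = as.list(r$antecedent),
           consequent = r$consequent, n_match_pos = r$n_match_pos,
           n_match_neg = r$n_match_neg, predominance = r$predominance,
           provenance = r$provenance)
    }),
    variables = .variables_to_list(rb$variables),
    output = lapply(rb$output, .mf_to_list),
    threshold = rb$threshold, grid_points = rb$grid_points,
    scheme = .scheme_to_list(rb$scheme),
    min_support = rb$min_support,
    predominance_threshold = rb$predominance_threshold,
    n_train = rb$n_train
  )
}

.rulebase_from_list <- function(l) {
  rb <- list(
    rules = lapply(l$rules, function(r) {
      ante <- unlist(r$antecedent)
      list(antecedent = ante, consequent = r$consequent,
           n_match_pos = as.integer(r$n_match_pos),
           n_match_neg = as.integer(r$n_match_neg),
           predominance = as.numeric(r$predominance),
           provenance = unlist(r$provenance), id = r$id)
    }),
    variables = .variables_from_list(l$variables),
    output = lapply(l$output, .mf_from_list),
    threshold = as.numeric(l$threshold),
    grid_points = as.integer(l$grid_points),
    scheme = .scheme_from_list(l$scheme),
    min_support = as.numeric(l$min_support),
    predominance_threshold = as.numeric(l$predominance_threshold),
    n_train = as.integer(l$n_train)
  )
  class(rb) <- "fuzzy_rulebase"
  rb
}

#' Write / read a rule base as human-readable JSON
#'
#' The serialized rule base is the explainability contract of the model:
#' every rule's antecedent items, per-class match counts, predominance,
#' consequent, and cluster provenance are stored in plain JSON.
#'
#' @param rulebase A `fuzzy_rulebase`.
#' @param path Output / input file path.
#' @return `write_rulebase` returns `path` invisibly; `read_rulebase` the
#'   rule base.
#' @export
write_rulebase <- function(rulebase, path) {
  jsonlite::write_json(.rulebase_to_list(rulebase), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rulebase
#' @export
read_rulebase <- function(path) {
  .rulebase_from_list(jsonlite::read_json(path))
}
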