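# Feature encoding shared by the SOM and the SVM stage: one-hot categoricals,
# min-max scaled numerics, statistics frozen from the training cohort.

#' Build a feature encoder from a training cohort
#'
#' Freezes the encoding of the six classifier input variables into a numeric
#' vector: categorical variables are one-hot encoded (one coordinate per
#' level) and numeric variables min-max scaled to `[0, 1]` using the training
#' minima and maxima, so all coordinates are on comparable scales for
#' Euclidean winner search and the linear kernel.
#'
#' @param train Training cohort data frame.
#' @param variables Variables to encode (default: the six classifier inputs).
#' @return An object of class `fb_encoder` with the frozen statistics.
#' @export
make_encoder <- function(train, variables = fis_variables()) {
  num <- intersect(variables, .gower_numeric)
  cat <- intersect(variables, .gower_categorical)
  mins <- vapply(num, function(v) min(train[[v]], na.rm = TRUE), numeric(1))
  maxs <- vapply(num, function(v) max(train[[v]], na.rm = TRUE), numeric(1))
  # a variable constant in training carries no information: give it unit
  # range so it encodes to a constant 0 instead of 0/0
  maxs[maxs - mins <= 0] <- mins[maxs - mins <= 0] + 1
  levels <- .cat_levels[cat]
  dims <- character(0)
  for (v in num) dims <- c(dims, v)
  for (v in cat) dims <- c(dims, paste(v, levels[[v]], sep = "="))
  enc <- list(variables = variables, numeric = num, categorical = cat,
              mins = mins, maxs = maxs, levels = levels, dims = dims)
  class(enc) <- "fb_encoder"
  enc
}

#' Encode patient records as numeric vectors
#'
#' Applies a frozen [make_encoder()] spec: numerics scaled by the training
#' min-max statistics (a record at the training maximum maps to 1), one-hot
#' categoricals. Deterministic; identical records give identical vectors.
#'
#' @param records Cohort data frame (one or more rows).
#' @param encoder An `fb_encoder`.
#' @return Numeric matrix, one row per record, columns named by `encoder$dims`.
#' @export
encode_features <- function(records, encoder) {
  stopifnot(inherits(encoder, "fb_encoder"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (v in encoder$variables) {
    if (!v %in% names(records)) stop("missing variable: ", v)
    if (anyNA(records[[v]])) stop("missing value(s) in variable: ", v)
  }
  n <- nrow(records)
  out <- matrix(0, nrow = n, ncol = length(encoder$dims),
                dimnames = list(NULL, encoder$dims))
  for (v in encoder$numeric) {
    out[, v] <- (records[[v]] - encoder$mins[[v]]) /
      (encoder$maxs[[v]] - encoder$mins[[v]])
  }
  for (v in encoder$categorical) {
    for (lv in encoder$levels[[v]]) {
      out[, paste(v, lv, sep = "=")] <- as.numeric(records[[v]] == lv)
    }
  }
  out
}
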