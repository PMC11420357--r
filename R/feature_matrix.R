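#' Patient-by-feature matrix with explicit missingness
#'
#' The central container of the preprocessing chain: a numeric matrix of
#' patients (rows) by clinical features (columns), a logical mask marking
#' missing entries (which also appear as `NA` in `values`), and per-feature
#' metadata (`name`, `type` where type is `"binary"` or `"continuous"`).
#'
#' @param values Numeric matrix, `NA` for missing entries.
#' @param feature_types Character vector, one of `"binary"`, `"continuous"`
#'   per column. Recycled if length 1.
#' @param patient_ids Row identifiers; defaults to `1:nrow(values)` as
#'   character.
#'
#' @return An object of class `feature_matrix` with elements `values`,
#'   `missing_mask`, `feature_meta` and `patient_ids`.
#' @export
feature_matrix <- function(values, feature_types = "continuous",
                           patient_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)) && ncol(values) > 0) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) {
    stop("feature names must be unique")
  }
  if (is.null(patient_ids)) {
    patient_ids <- as.character(seq_len(nrow(values)))
  }
  if (length(patient_ids) != nrow(values)) {
    stop("patient_ids must match the number of rows")
  }
  feature_types <- rep_len(feature_types, ncol(values))
  if (!all(feature_types %in% c("binary", "continuous"))) {
    stop("feature types must be 'binary' or 'continuous'")
  }
  structure(
    list(
      values = values,
      missing_mask = is.na(values),
      feature_meta = data.frame(
        name = if (is.null(colnames(values))) character(0) else colnames(values),
        type = feature_types,
        stringsAsFactors = FALSE
      ),
      patient_ids = as.character(patient_ids)
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "feature_matrix: %d patients x %d features (%.1f%% missing)\n",
    nrow(x$values), ncol(x$values),
    100 * mean(x$missing_mask)
  ))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Per-feature missing fraction
#'
#' @param m A `feature_matrix`.
#' @return Named numeric vector of missing fractions per feature.
#' @export
missing_fraction <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  colMeans(m$missing_mask)
}

#' Read and write the features.csv dialect
#'
#' `features.csv` holds a `patient_id` column plus one column per feature;
#' an empty cell encodes a missing value. Feature types are recovered from
#' the data when reading: a column whose observed values are all 0/1 is
#' treated as binary.
#'
#' @param m A `feature_matrix`.
#' @param path File path.
#' @return `read_features` returns a `feature_matrix`;
#'   `write_features` returns `path` invisibly.
#' @export
write_features <- function(m, path) {
  stopifnot(inherits(m, "feature_matrix"))
  df <- data.frame(patient_id = m$patient_ids, m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE, na.strings = "")
  if (!"patient_id" %in% names(df)) stop("features.csv needs a patient_id column")
  ids <- as.character(df$patient_id)
  vals <- as.matrix(df[setdiff(names(df), "patient_id")])
  storage.mode(vals) <- "double"
  types <- vapply(seq_len(ncol(vals)), function(j) {
    obs <- vals[!is.na(vals[, j]), j]
    if (length(obs) > 0 && all(obs %in% c(0, 1))) "binary" else "continuous"
  }, character(1))
  feature_matrix(vals, types, ids)
}
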