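#' Discard features with excessive missingness
#'
#' Removes every feature whose missing fraction is greater than or equal to
#' `threshold` (the rule is closed at the boundary: exactly 40% missing is
#' discarded under the default). Survivor order is preserved.
#'
#' @param m A [feature_matrix()].
#' @param threshold Missing-fraction cutoff in (0, 1], default 0.40.
#' @return A list with `matrix` (the filtered `feature_matrix`) and
#'   `discarded` (character vector of removed feature names). If no feature
#'   survives, a warning is raised and the matrix has zero columns.
#' @export
filter_features <- function(m, threshold = 0.40) {
  stopifnot(inherits(m, "feature_matrix"))
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must lie in (0, 1]")
  }
  frac <- missing_fraction(m)
  drop <- frac >= threshold
  discarded <- names(frac)[drop]
  keep <- which(!drop)
  out <- feature_matrix(m$values[, keep, drop = FALSE],
                        m$feature_meta$type[keep],
                        m$patient_ids)
  if (ncol(out$values) == 0 && ncol(m$values) > 0) {
    warning("all features discarded by the missingness screen")
  }
  list(matrix = out, discarded = discarded)
}

#' Mean imputation
#'
#' Replaces each missing entry with the mean of the feature's observed
#' values; observed entries are untouched and the missingness mask is
#' cleared. Binary features are imputed with their observed mean (a
#' fraction), the same rule as continuous ones.
#'
#' @param m A [feature_matrix()] in which every feature has at least one
#'   observed value.
#' @return A complete `feature_matrix`.
#' @export
impute_mean <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  vals <- m$values
  for (j in seq_len(ncol(vals))) {
    miss <- m$missing_mask[, j]
    if (!any(miss)) next
    if (all(miss)) {
      stop(sprintf("feature '%s' has no observed values; filter it first",
                   colnames(vals)[j]))
    }
    vals[miss, j] <- mean(vals[!miss, j])
  }
  feature_matrix(vals, m$feature_meta$type, m$patient_ids)
}

#' Z-score transformation
#'
#' Centers each feature to mean 0 and scales to sample (n-1) standard
#' deviation 1. Zero-variance features map to all-zero columns rather than
#' NaN, so constant binary features survive small cohorts.
#'
#' @param m A complete [feature_matrix()] (no missing entries).
#' @return A standardized `feature_matrix`.
#' @export
zscore <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  if (any(m$missing_mask)) stop("zscore requires a complete matrix; impute first")
  vals <- m$values
  if (nrow(vals) > 0) {
    ctr <- colMeans(vals)
    sdv <- apply(vals, 2, stats::sd)
    vals <- sweep(vals, 2, ctr)
    ok <- is.finite(sdv) & sdv > 0
    vals[, ok] <- sweep(vals[, ok, drop = FALSE], 2, sdv[ok], "/")
    vals[, !ok] <- 0
  }
  feature_matrix(vals, m$feature_meta$type, m$patient_ids)
}

#' Run the full screening-imputation-scaling chain
#'
#' [filter_features()], then [impute_mean()], then [zscore()].
#'
#' @inheritParams filter_features
#' @return A list with `matrix` (complete, standardized) and `discarded`.
#' @export
preprocess <- function(m, threshold = 0.40) {
  flt <- filter_features(m, threshold)
  list(matrix = zscore(impute_mean(flt$matrix)), discarded = flt$discarded)
}
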