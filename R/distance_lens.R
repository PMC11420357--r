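#' Normalized-correlation distance between patients
#'
#' The patient-patient distance used to build the similarity network:
#' `d(i, j) = 1 - r(x_i, x_j)` where `r` is the Pearson correlation between
#' the two patients' feature vectors (each centered across its own
#' features). Distances lie in `[0, 2]`: identical profiles give 0,
#' perfectly anticorrelated profiles give 2. A patient whose feature vector
#' has zero variance is assigned correlation 0 (distance 1) against every
#' other patient and distance 0 to itself.
#'
#' @param m A complete [feature_matrix()] with at least two features.
#' @return An `n x n` symmetric matrix with zero diagonal; patient ids as
#'   dimnames.
#' @export
normalized_correlation_distance <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  if (any(m$missing_mask)) stop("distance requires a complete matrix")
  x <- m$values
  if (ncol(x) < 2) stop("normalized correlation needs at least 2 features")
  rowsd <- apply(x, 1, stats::sd)
  degenerate <- !is.finite(rowsd) | rowsd == 0
  r <- suppressWarnings(stats::cor(t(x)))
  r[degenerate, ] <- 0
  r[, degenerate] <- 0
  d <- 1 - r
  diag(d) <- 0
  d[d < 0] <- 0
  d[d > 2] <- 2
  d <- (d + t(d)) / 2
  dimnames(d) <- list(m$patient_ids, m$patient_ids)
  d
}

#' Two classical multidimensional-scaling lenses
#'
#' Projects the distance matrix to the plane by classical (Torgerson) metric
#' MDS: double-center `-D^2/2`, take the two leading non-negative
#' eigenpairs, and scale each eigenvector by the square root of its
#' eigenvalue. The two coordinates are the Mapper lens values. The
#' decomposition is deterministic; to fix the residual sign ambiguity each
#' lens column is flipped so that its largest-magnitude entry is positive.
#'
#' @param d Symmetric distance matrix as from
#'   [normalized_correlation_distance()].
#' @return An `n x 2` matrix of lens coordinates (columns `lens1`, `lens2`),
#'   row names carrying the patient ids. If fewer than two positive
#'   eigenvalues exist the missing lens is zero-padded with a warning.
#' @export
mds_lenses <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  fit <- suppressWarnings(
    stats::cmdscale(d, k = min(2, max(1, n - 1)), eig = TRUE)
  )
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < 2) {
    warning("fewer than 2 positive eigenvalues; zero-padding the missing lens")
    pad <- matrix(0, n, 2 - if (is.null(pts)) 0 else ncol(pts))
    pts <- cbind(if (is.null(pts)) NULL else pts, pad)
  }
  pts <- pts[, 1:2, drop = FALSE]
  for (k in 1:2) {
    col <- pts[, k]
    if (any(col != 0)) {
      top <- which.max(abs(col))
      if (col[top] < 0) pts[, k] <- -col
    }
  }
  colnames(pts) <- c("lens1", "lens2")
  rownames(pts) <- rownames(d)
  pts
}

#' Export lens coordinates as CSV
#'
#' @param lens Matrix from [mds_lenses()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lenses <- function(lens, path) {
  df <- data.frame(patient_id = rownames(lens), lens1 = lens[, 1],
                   lens2 = lens[, 2], stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
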