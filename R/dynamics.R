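#' Delta (rate-of-change) features
#'
#' Regression-based delta coefficients over a window of `M` rows on each
#' side: row r of the result is
#' `sum_{m=1..M} m * (x[r+m, ] - x[r-m, ]) / (2 * sum_{m=1..M} m^2)`,
#' with out-of-range indices clamped to the first/last row (edge
#' replication, the usual convention in frame-based speech processing).
#' A constant column therefore has an all-zero delta, and interior rows
#' of a linear ramp recover its slope exactly.
#'
#' @param x numeric R x D matrix (R >= 1), one row per time index.
#' @param M window half-width in rows; the default `M = 2` gives a
#'   5-sample window.
#' @return An R x D matrix of delta features.
#' @export
#' @examples
#' deltaFeatures(matrix(1:10 * 2, ncol = 1))  # slope 2 in the interior
deltaFeatures <- function(x, M = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L) stop("empty feature matrix", call. = FALSE)
  if (!all(is.finite(x))) stop("feature matrix must be finite", call. = FALSE)
  M <- as.integer(M)
  if (M < 1L) stop("window half-width M must be >= 1", call. = FALSE)
  R <- nrow(x)
  num <- matrix(0, R, ncol(x))
  r <- seq_len(R)
  for (m in seq_len(M)) {
    fwd <- pmin(r + m, R)
    bwd <- pmax(r - m, 1L)
    num <- num + m * (x[fwd, , drop = FALSE] - x[bwd, , drop = FALSE])
  }
  num / (2 * sum(seq_len(M)^2))
}

#' Append delta and acceleration features
#'
#' Expands an R x D matrix of static features to R x 3D by appending the
#' delta features and the acceleration features (the delta operator
#' applied to the delta matrix, same window and edge rule). Applied to
#' the N x 10 cardiovascular matrix this yields the 30-dim dynamic set;
#' applied at frame level to the L x 3 formant matrix it yields the 9
#' tracks summarised by the 90-dim beat statistics.
#'
#' @inheritParams deltaFeatures
#' @return An R x 3D matrix, columns ordered \[static | delta |
#'   acceleration\]; input column names get `d_`/`a_` prefixed copies.
#' @export
expandDynamics <- function(x, M = 2L) {
  x <- as.matrix(x)
  d <- deltaFeatures(x, M)
  a <- deltaFeatures(d, M)
  out <- cbind(x, d, a)
  if (!is.null(colnames(x)))
    colnames(out) <- c(colnames(x), paste0("d_", colnames(x)),
                       paste0("a_", colnames(x)))
  out
}
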