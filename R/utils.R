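#' Circular mean resultant length
#'
#' @param theta angles in radians.
#' @return mean resultant length \eqn{\bar R \in [0, 1]}.
#' @keywords internal
resultant_length <- function(theta) {
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

#' Circular standard deviation of a set of angles
#'
#' Angular-deviation convention \eqn{\sqrt{2(1-\bar R)}} by default, with the
#' log form \eqn{\sqrt{-2\ln\bar R}} available. Reported in degrees.
#'
#' @param theta angles in radians.
#' @param form `"angular"` (default) or `"log"`.
#' @param degrees return degrees (default) or radians.
#' @return circular standard deviation.
#' @examples
#' circ_sd(rep(0, 5))                      # 0
#' circ_sd(2 * pi * (0:4) / 5)             # maximal spread: sqrt(2) rad
#' @export
circ_sd <- function(theta, form = c("angular", "log"), degrees = TRUE) {
  form <- match.arg(form)
  rbar <- resultant_length(theta)
  s <- switch(form,
    angular = sqrt(2 * (1 - rbar)),
    log = sqrt(-2 * log(max(rbar, .Machine$double.xmin)))
  )
  if (degrees) s * 180 / pi else s
}

#' Convert a phase sample (0-99) to radians
#' @param phase phase sample on the 100-sample gait grid.
#' @return angle in radians.
#' @export
phase_to_rad <- function(phase) phase * 2 * pi / 100

#' Maximum measurable manifold dimensionality for a smoothed task epoch
#'
#' The number of independently resolvable time bins in an epoch is bounded
#' by the epoch duration divided by the width of the rate-smoothing filter;
#' that bound caps the PCA dimensionality a single task can exhibit.
#'
#' @param duration_ms epoch (mean gait cycle) duration in milliseconds.
#' @param filter_width_ms smoothing filter width in milliseconds.
#' @return ceiling estimate, rounded to one decimal.
#' @examples
#' dimensionality_ceiling(942, 128)  # 7.4
#' @export
dimensionality_ceiling <- function(duration_ms, filter_width_ms) {
  stopifnot(duration_ms > 0, filter_width_ms > 0)
  round(duration_ms / filter_width_ms, 1)
}

#' Orthonormalize matrix columns
#' @param M numeric matrix.
#' @return matrix with orthonormal columns spanning `colspace(M)`.
#' @keywords internal
orthonormalize <- function(M) {
  s <- svd(M)
  keep <- s$d > max(dim(M)) * .Machine$double.eps * max(s$d, 1)
  s$u[, keep, drop = FALSE]
}

#' Haar-random orthonormal basis
#' @param n ambient dimension.
#' @param m subspace dimension.
#' @return `n x m` matrix with orthonormal columns.
#' @keywords internal
random_subspace_basis <- function(n, m) {
  orthonormalize(matrix(stats::rnorm(n * m), n, m))
}

# truncated normal draw via rejection (bounds are loose; cheap)
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
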