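#' PCA manifold model and dimensionality
#'
#' Dimensionality is the smallest number of leading principal components
#' whose cumulative variance is strictly greater than `threshold`.
#'
#' @param X channels x samples matrix (centered internally per channel).
#' @param threshold cumulative-variance threshold (default 0.90).
#' @return list with `model` (class `manifold_model`: per-channel `mean`,
#'   orthonormal `encoder` (m x n), `decoder` (n x m), `eigenvalues`,
#'   `threshold`, `d`) and `d`.
#' @examples
#' X <- diag(3) %*% matrix(rnorm(300), 3)   # 3 equal-variance axes
#' pca_dimensionality(X)$d
#' @export
pca_dimensionality <- function(X, threshold = 0.90) {
  stopifnot(is.matrix(X), ncol(X) >= 2)
  mu <- rowMeans(X)
  Xc <- X - mu
  if (all(abs(Xc) < 1e-300)) stop("all-zero data matrix")
  e <- eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  d <- dim_from_eigenvalues(ev, threshold)
  enc <- t(e$vectors[, seq_len(d), drop = FALSE])
  model <- list(mean = mu, encoder = enc, decoder = t(enc),
                eigenvalues = ev, threshold = threshold, d = d)
  class(model) <- "manifold_model"
  list(model = model, d = d)
}

dim_from_eigenvalues <- function(ev, threshold) {
  ev <- pmax(ev, 0)
  cv <- cumsum(ev) / sum(ev)
  # strict exceedance with a guard so exact-boundary spectra (cumulative
  # variance equal to the threshold in exact arithmetic) are not tipped
  # over by floating-point rounding
  as.integer(which(cv > threshold + 1e-9)[1])
}

#' Concatenate per-cycle warped activity into a channels x samples matrix
#'
#' Single-cycle (not trial-averaged) activity; the dimensionality-ceiling
#' argument reasons about per-cycle activity.
#'
#' @param pt `perigait_tensor`.
#' @param tasks task indices to include (default all).
#' @param channels channel indices (default all non-constant channels).
#' @return channels x (100 * total cycles) matrix.
#' @export
tensor_to_matrix <- function(pt, tasks = NULL, channels = NULL) {
  tasks <- tasks %||% seq_along(pt$tasks)
  channels <- channels %||% setdiff(seq_len(dim(pt$tensor)[1]),
                                    pt$constant_channels %||% integer(0))
  blocks <- lapply(tasks, function(ti) {
    nc <- pt$n_cycles[ti]
    m <- pt$tensor[channels, ti, seq_len(nc), , drop = FALSE]
    dim(m) <- c(length(channels), nc * 100)
    m
  })
  do.call(cbind, blocks)
}

# Per-task sufficient statistics (second moments + means) so that any
# channel-subset / task-subset PCA is exact without touching raw samples.
task_moments <- function(pt, channels = NULL) {
  channels <- channels %||% setdiff(seq_len(dim(pt$tensor)[1]),
                                    pt$constant_channels %||% integer(0))
  lapply(seq_along(pt$tasks), function(ti) {
    X <- tensor_to_matrix(pt, tasks = ti, channels = channels)
    list(M = tcrossprod(X), mu = rowMeans(X), n = ncol(X))
  })
}

# eigenvalues of the pooled covariance of tasks `ts` over channel subset `s`
pooled_eigen <- function(mom, ts, s) {
  N <- sum(vapply(mom[ts], `[[`, numeric(1), "n"))
  mu <- Reduce(`+`, lapply(mom[ts], function(m) m$n * m$mu[s])) / N
  S <- Reduce(`+`, lapply(mom[ts], function(m) m$M[s, s, drop = FALSE]))
  C <- S / N - tcrossprod(mu)
  eigen(C, symmetric = TRUE, only.values = TRUE)$values
}

#' Dimensionality battery: single-task, all-task, delta, leave-one-out
#'
#' Each quantity is the mean over `reps` random draws of `n_sub` channels
#' (seeded), matching the channel-count equalization used when comparing
#' regions. `delta_dim` is the all-task dimensionality minus the mean
#' single-task dimensionality; leave-one-out values are the all-task
#' dimensionality minus the all-but-one dimensionality per excluded task.
#'
#' @param pt `perigait_tensor`.
#' @param n_sub channels per draw (default 32). If the region has exactly
#'   `n_sub` usable channels the battery collapses to a single draw.
#' @param reps number of random channel draws (default 1000).
#' @param threshold cumulative-variance threshold.
#' @param seed RNG seed for the channel draws.
#' @return list with `single_task_d` (mean per task), `all_task_d`,
#'   `delta_dim`, `leave_one_out` (per excluded task), `reps`, `n_sub`.
#' @export
dimensionality_battery <- function(pt, n_sub = 32, reps = 1000,
                                   threshold = 0.90, seed = 1) {
  usable <- setdiff(seq_len(dim(pt$tensor)[1]),
                    pt$constant_channels %||% integer(0))
  if (length(usable) < n_sub) stop("fewer usable channels than n_sub")
  if (reps < 1) stop("reps must be >= 1")
  n_task <- length(pt$tasks)
  mom <- task_moments(pt, channels = usable)
  if (length(usable) == n_sub) reps <- 1
  rng <- local({ set.seed(seed); replicate(reps, sample(length(usable), n_sub),
                                           simplify = FALSE) })
  single <- matrix(0, reps, n_task)
  alltask <- numeric(reps)
  loo <- matrix(0, reps, n_task)
  for (r in seq_len(reps)) {
    s <- rng[[r]]
    for (ti in seq_len(n_task)) {
      single[r, ti] <- dim_from_eigenvalues(pooled_eigen(mom, ti, s), threshold)
    }
    alltask[r] <- dim_from_eigenvalues(pooled_eigen(mom, seq_len(n_task), s),
                                       threshold)
    for (ti in seq_len(n_task)) {
      loo[r, ti] <- dim_from_eigenvalues(
        pooled_eigen(mom, setdiff(seq_len(n_task), ti), s), threshold)
    }
  }
  list(
    single_task_d = colMeans(single),
    all_task_d = mean(alltask),
    delta_dim = mean(alltask) - mean(single),
    leave_one_out = mean(alltask) - colMeans(loo),
    reps = reps, n_sub = n_sub
  )
}

#' Fraction of variance captured by projecting data into a subspace
#'
#' Reconstruction-error form: `1 - ||X - D E X||^2 / ||X||^2` with
#' `E = t(basis)`, `D = basis`; `X` is centered per channel first.
#'
#' @param X channels x samples matrix.
#' @param basis n x m orthonormal basis.
#' @return captured-variance fraction in `[0, 1]`.
#' @export
captured_variance_fraction <- function(X, basis) {
  Xc <- X - rowMeans(X)
  tot <- sum(Xc^2)
  if (tot == 0) stop("zero-variance data")
  proj <- basis %*% crossprod(basis, Xc)
  1 - sum((Xc - proj)^2) / tot
}

#' Alignment index between two single-task manifolds
#'
#' Task a's mean peri-gait activity is projected into task b's m-dimensional
#' manifold; the captured-variance fraction is (by default) normalized by the
#' fraction captured when projecting into task a's own m-dimensional
#' manifold. `normalize = "none"` returns the raw captured fraction.
#'
#' @param pt `perigait_tensor`.
#' @param task_a,task_b task indices (data from a, manifold from b).
#' @param m common manifold dimension; default is the larger of the two
#'   tasks' 90% dimensionalities.
#' @param normalize `"self"` (default) or `"none"`.
#' @return alignment index in `[0, 1]` (can marginally exceed 1 when b's
#'   manifold captures task a better than its own, `normalize = "self"`).
#' @export
alignment_index <- function(pt, task_a, task_b, m = NULL,
                            normalize = c("self", "none")) {
  normalize <- match.arg(normalize)
  channels <- setdiff(seq_len(dim(pt$tensor)[1]),
                      pt$constant_channels %||% integer(0))
  Xa <- pt$trial_avg[channels, task_a, ]
  Xb <- pt$trial_avg[channels, task_b, ]
  pa <- pca_dimensionality(Xa); pb <- pca_dimensionality(Xb)
  m <- m %||% max(pa$d, pb$d)
  if (m > length(channels)) stop("m exceeds the number of channels")
  rk <- function(p) sum(p$model$eigenvalues > 1e-12 * sum(p$model$eigenvalues))
  if (m > min(rk(pa), rk(pb))) stop("m exceeds the rank of a task's data")
  basis_b <- manifold_basis(Xb, m)
  num <- captured_variance_fraction(Xa, basis_b)
  if (normalize == "none") return(num)
  den <- captured_variance_fraction(Xa, manifold_basis(Xa, m))
  num / den
}

manifold_basis <- function(X, m) {
  Xc <- X - rowMeans(X)
  e <- eigen(tcrossprod(Xc), symmetric = TRUE)
  e$vectors[, seq_len(m), drop = FALSE]
}

#' Session-level alignment index
#'
#' Mean alignment index over all ordered task pairs (a != b).
#'
#' @inheritParams alignment_index
#' @return list with `pairs` data.frame and `mean_ai`.
#' @export
alignment_index_session <- function(pt, m = NULL,
                                    normalize = c("self", "none")) {
  normalize <- match.arg(normalize)
  n_task <- length(pt$tasks)
  grid <- expand.grid(a = seq_len(n_task), b = seq_len(n_task))
  grid <- grid[grid$a != grid$b, ]
  grid$ai <- mapply(function(a, b) {
    alignment_index(pt, a, b, m = m, normalize = normalize)
  }, grid$a, grid$b)
  list(pairs = grid, mean_ai = mean(grid$ai))
}
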