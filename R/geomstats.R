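#' Subspace object
#'
#' @param basis n x m matrix with orthonormal columns.
#' @param kind one of "task-independent", "task-dependent", "communication",
#'   "random".
#' @param region optional region tag.
#' @return object of class `subspace`.
#' @export
subspace <- function(basis, kind = c("task-independent", "task-dependent",
                                     "communication", "random"),
                     region = NULL) {
  kind <- match.arg(kind)
  basis <- as.matrix(basis)
  if (ncol(basis) == 0) stop("zero-dimensional subspace")
  G <- crossprod(basis)
  if (max(abs(G - diag(ncol(basis)))) > 1e-8) {
    stop("basis columns are not orthonormal")
  }
  structure(list(basis = basis, kind = kind, region = region),
            class = "subspace")
}

#' Principal angles between two subspaces
#'
#' Arc-cosines of the singular values of `W_a^T W_b`, clipped to
#' `[0, 90]` degrees, ascending; `min(m_a, m_b)` angles are returned.
#'
#' @param A,B `subspace` objects (or orthonormal basis matrices).
#' @return numeric vector of angles in degrees, ascending.
#' @examples
#' I3 <- diag(3)
#' principal_angles(subspace(I3[, 1:2], "random"),
#'                  subspace(I3[, 1:2], "random"))  # 0, 0
#' @export
principal_angles <- function(A, B) {
  Wa <- if (inherits(A, "subspace")) A$basis else A
  Wb <- if (inherits(B, "subspace")) B$basis else B
  s <- svd(crossprod(Wa, Wb), nu = 0, nv = 0)$d
  sort(acos(pmin(pmax(s, -1), 1)) * 180 / pi)
}

#' Delta-angles statistic
#'
#' Mean principal angle between the communication subspace and the leading
#' task-dependent subspace, minus the mean principal angle to the leading
#' task-independent subspace. Positive values mean the communication
#' subspace is preferentially aligned with the task-independent subspace.
#'
#' @param comm communication `subspace`.
#' @param td5,ti5 `subspace`s built from exactly 5 leading task-dependent /
#'   task-independent modes.
#' @return Delta in degrees.
#' @export
delta_angles <- function(comm, td5, ti5) {
  if (is.null(td5) || is.null(ti5) || is.null(comm)) {
    stop("missing subspace argument")
  }
  for (nm in c("td5", "ti5")) {
    b <- get(nm)
    if (ncol(b$basis) != 5) {
      stop(nm, " must have exactly 5 modes, got ", ncol(b$basis))
    }
  }
  mean(principal_angles(comm, td5)) - mean(principal_angles(comm, ti5))
}

#' Monte-Carlo p-value with the add-one convention
#'
#' `p = (1 + #\{null at least as extreme\}) / (1 + N)`; the floor is
#' `1 / (N + 1)` (0.0005 at N = 2000).
#'
#' @param observed observed statistic.
#' @param null numeric vector of null draws.
#' @param direction `"greater"` or `"less"`.
#' @return p-value.
#' @export
mc_pvalue <- function(observed, null, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(null) == 0) stop("empty null sample")
  extreme <- switch(direction,
    greater = sum(null >= observed),
    less = sum(null <= observed)
  )
  (1 + extreme) / (1 + length(null))
}

#' Cyclically rotate every warped trace by a random gait phase
#'
#' Each (channel, task, cycle) 100-sample trace is advanced by an
#' independent shift drawn uniformly from 0-99.
#'
#' @param pt `perigait_tensor`.
#' @return `perigait_tensor` with shuffled traces (trial averages updated).
#' @export
phase_shuffle <- function(pt) {
  tn <- pt$tensor
  d <- dim(tn)
  for (ti in seq_len(d[2])) {
    nc <- pt$n_cycles[ti]
    sh <- matrix(sample(0:99, d[1] * nc, replace = TRUE), d[1], nc)
    for (ci in seq_len(nc)) {
      for (ch in seq_len(d[1])) {
        s <- sh[ch, ci]
        if (s > 0) {
          v <- tn[ch, ti, ci, ]
          tn[ch, ti, ci, ] <- c(v[(s + 1):100], v[1:s])
        }
      }
    }
  }
  pt$tensor <- tn
  pt$trial_avg <- trial_average(tn)
  pt
}

# k bootstrap pseudo-datasets of one task's cycles, stacked as pseudo-tasks
bootstrap_pseudo_tasks <- function(pt, task, k) {
  nc <- pt$n_cycles[task]
  d <- dim(pt$tensor)
  tn <- array(NA_real_, c(d[1], k, nc, 100))
  for (j in seq_len(k)) {
    draw <- sample(nc, nc, replace = TRUE)
    tn[, j, , ] <- pt$tensor[, task, draw, , drop = FALSE]
  }
  out <- list(
    tensor = tn,
    trial_avg = trial_average(tn),
    tasks = seq_len(k), n_cycles = rep(nc, k),
    rejections = pt$rejections[0, ],
    constant_channels = pt$constant_channels
  )
  class(out) <- "perigait_tensor"
  out
}

#' Null-distribution engine for the pipeline's statistics
#'
#' Generates an N-sample null of a statistic under one of the resampling /
#' randomization schemes used throughout the analysis:
#' \describe{
#'   \item{bootstrap-split}{per task, two bootstrap pseudo-datasets of the
#'     task's cycles are treated as two pseudo-tasks; `statistic` is applied
#'     to the pseudo-tensor and the result averaged across tasks (noise
#'     contribution for correlation / alignment-index statistics).}
#'   \item{bootstrap-5}{same with five pseudo-datasets (noise contribution
#'     for PGP s.d. / task-independent-variance statistics).}
#'   \item{phase-shuffle}{every channel x cycle warped trace is advanced by
#'     a uniform random gait phase; `statistic` is applied to the shuffled
#'     tensor (chance level).}
#'   \item{pgp-uniform}{five angles drawn uniformly on the circle; the draw
#'     is their circular standard deviation in degrees (`statistic`
#'     ignored).}
#'   \item{subspace-random}{`statistic` is applied to a Haar-random
#'     orthonormal `n x m` basis (dimensions from `data$n`, `data$m`).}
#'   \item{target-shuffle}{`statistic` is applied to a phase-shuffled copy
#'     of the target tensor `data` (caller refits the communication model
#'     inside `statistic`).}
#' }
#'
#' @param data a `perigait_tensor` for tensor modes, a list `list(n=, m=)`
#'   for `subspace-random`, or anything `statistic` understands for
#'   `target-shuffle`; ignored for `pgp-uniform`.
#' @param statistic function of the resampled object.
#' @param mode one of the modes above.
#' @param N null sample size (default 2000).
#' @param seed RNG seed.
#' @param observed observed value (optional; needed for a p-value).
#' @param direction alternative direction for the p-value.
#' @return object of class `stat_result`: `observed`, `null`, `p`,
#'   `direction`, `mode`, `N`, `seed`, and the null mean / sd / sem.
#' @export
null_engine <- function(data, statistic = NULL,
                        mode = c("bootstrap-split", "bootstrap-5",
                                 "phase-shuffle", "pgp-uniform",
                                 "subspace-random", "target-shuffle"),
                        N = 2000, seed = 1, observed = NULL,
                        direction = c("greater", "less")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  tensor_modes <- c("bootstrap-split", "bootstrap-5", "phase-shuffle",
                    "target-shuffle")
  if (mode %in% tensor_modes || mode == "subspace-random") {
    if (is.null(statistic)) stop("statistic required for mode ", mode)
  }
  set.seed(seed)
  null <- vapply(seq_len(N), function(i) {
    switch(mode,
      "pgp-uniform" = circ_sd(stats::runif(5, 0, 2 * pi)),
      "bootstrap-split" = {
        vals <- vapply(seq_along(data$tasks), function(tk) {
          statistic(bootstrap_pseudo_tasks(data, tk, 2))
        }, numeric(1))
        mean(vals)
      },
      "bootstrap-5" = {
        vals <- vapply(seq_along(data$tasks), function(tk) {
          statistic(bootstrap_pseudo_tasks(data, tk, 5))
        }, numeric(1))
        mean(vals)
      },
      "phase-shuffle" = statistic(phase_shuffle(data)),
      "subspace-random" = statistic(random_subspace_basis(data$n, data$m)),
      "target-shuffle" = statistic(phase_shuffle(data))
    )
  }, numeric(1))
  p <- if (!is.null(observed)) mc_pvalue(observed, null, direction) else NA_real_
  structure(list(
    observed = observed, null = null, p = p, direction = direction,
    mode = mode, N = N, seed = seed,
    null_mean = mean(null), null_sd = stats::sd(null),
    null_sem = stats::sd(null) / sqrt(N)
  ), class = "stat_result")
}

#' Serialize a stat_result to a one-row data.frame
#' @param x `stat_result`.
#' @return data.frame with observed value, p, null summaries, mode, seed, N.
#' @export
stat_result_row <- function(x) {
  data.frame(observed = x$observed %||% NA_real_, p = x$p,
             null_mean = x$null_mean, null_sd = x$null_sd,
             null_sem = x$null_sem, mode = x$mode,
             direction = x$direction, N = x$N, seed = x$seed)
}
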