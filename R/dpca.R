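#' Marginalize trial-averaged peri-gait activity into task-independent and
#' task-dependent parts
#'
#' After removing each channel's overall mean, the task-independent part is
#' the across-task mean at each phase (replicated across tasks) and the
#' task-dependent part is the remainder. The two parts are orthogonal and
#' sum exactly to the mean-centered tensor.
#'
#' @param x `perigait_tensor` or a channels x tasks x 100 array of
#'   trial-averaged activity.
#' @return list with arrays `X` (centered), `X_ti`, `X_td`
#'   (channels x tasks x 100) and `channels` used.
#' @export
marginalize <- function(x) {
  if (inherits(x, "perigait_tensor")) {
    channels <- setdiff(seq_len(dim(x$tensor)[1]),
                        x$constant_channels %||% integer(0))
    A <- x$trial_avg[channels, , , drop = FALSE]
  } else {
    stopifnot(is.array(x), length(dim(x)) == 3)
    A <- x
    channels <- seq_len(dim(A)[1])
  }
  n_task <- dim(A)[2]
  if (n_task < 2) warning("single task: task-dependent part is identically zero")
  X <- A - c(apply(A, 1, mean))  # remove per-channel overall mean
  ti_prof <- apply(X, c(1, 3), mean)  # channels x 100
  X_ti <- aperm(array(ti_prof, c(dim(A)[1], 100, n_task)), c(1, 3, 2))
  list(X = X, X_ti = X_ti, X_td = X - X_ti, channels = channels)
}

unroll <- function(A) {
  # channels x tasks x 100 -> channels x (tasks * 100)
  matrix(A, nrow = dim(A)[1])
}

#' Demixed PCA with gait-phase (task-independent) and task marginalizations
#'
#' Per marginalization the loss `||X_theta - F D X||^2` is minimized in
#' closed form: a mu-ridge regression of `X_theta` on `X` followed by
#' projection onto the leading left singular vectors of the fitted
#' prediction. Modes from the two marginalizations are pooled and ordered by
#' total explained variance. Decoder axes are unit-norm; encoders carry the
#' least-squares reconstruction scale.
#'
#' @param x `perigait_tensor` or channels x tasks x 100 array.
#' @param n_modes_per_marg modes retained per marginalization (default 10,
#'   capped at the data rank).
#' @param mu ridge regularizer; default `1e-6 * ||X||^2 / n`.
#' @return object of class `dpca_decomposition`: per-mode `decoder` (n x K),
#'   `encoder` (n x K), `variance_table` data.frame (total/TI/TD percent per
#'   mode, label), marginalization totals, `residual_pct`, plus the
#'   marginalization arrays.
#' @export
fit_dpca <- function(x, n_modes_per_marg = 10, mu = NULL) {
  mg <- marginalize(x)
  X <- unroll(mg$X)
  n <- nrow(X)
  tot <- sum(X^2)
  if (tot == 0) stop("zero-variance data")
  mu <- mu %||% (1e-6 * tot / n)
  margs <- list(ti = unroll(mg$X_ti), td = unroll(mg$X_td))
  G <- tcrossprod(X) + mu * diag(n)
  sv_X <- svd(X, nu = 0, nv = 0)$d
  rank_X <- sum(sv_X > 1e-10 * max(sv_X))
  k <- min(n_modes_per_marg, rank_X)
  dec <- list(); enc <- list(); marg_of <- character(0)
  for (m in names(margs)) {
    A <- margs[[m]] %*% crossprod(X, solve(G))  # regression map X_theta ~ X
    fit <- A %*% X
    sv <- svd(fit, nu = k, nv = 0)
    U <- sv$u
    Draw <- crossprod(U, A)  # k x n decoders (before normalization)
    for (j in seq_len(k)) {
      dn <- sqrt(sum(Draw[j, ]^2))
      if (dn < 1e-12) next
      dec[[length(dec) + 1]] <- Draw[j, ] / dn
      enc[[length(enc) + 1]] <- U[, j] * dn
      marg_of <- c(marg_of, m)
    }
  }
  D <- do.call(cbind, dec)  # n x K decoder axes
  Fm <- do.call(cbind, enc)
  K <- ncol(D)
  v_ti <- numeric(K); v_td <- numeric(K)
  for (j in seq_len(K)) {
    fd <- function(M) Fm[, j, drop = FALSE] %*% crossprod(D[, j, drop = FALSE], M)
    v_ti[j] <- (sum(margs$ti^2) - sum((margs$ti - fd(margs$ti))^2)) / tot * 100
    v_td[j] <- (sum(margs$td^2) - sum((margs$td - fd(margs$td))^2)) / tot * 100
  }
  v_tot <- v_ti + v_td
  ord <- order(v_tot, decreasing = TRUE)
  D <- D[, ord, drop = FALSE]; Fm <- Fm[, ord, drop = FALSE]
  v_ti <- v_ti[ord]; v_td <- v_td[ord]; v_tot <- v_tot[ord]
  marg_of <- marg_of[ord]
  label <- ifelse(v_ti > 0.5 * v_tot, "task-independent", "task-dependent")
  # residual after sequentially deflating all task-independent modes (in
  # mode order) and then all task-dependent modes -- the same canonical
  # order a remove_modes() pass over both labels applies
  R <- X
  for (j in c(which(label == "task-independent"),
              which(label == "task-dependent"))) {
    R <- R - Fm[, j, drop = FALSE] %*% crossprod(D[, j, drop = FALSE], R)
  }
  residual_pct <- sum(R^2) / tot * 100
  out <- list(
    decoder = D, encoder = Fm,
    variance_table = data.frame(
      mode = seq_len(K), marginalization = marg_of,
      total_pct = v_tot, ti_pct = v_ti, td_pct = v_td, label = label
    ),
    marginalization_totals = c(
      ti = sum(margs$ti^2) / tot * 100,
      td = sum(margs$td^2) / tot * 100
    ),
    residual_pct = residual_pct,
    channels = mg$channels, X = mg$X, X_ti = mg$X_ti, X_td = mg$X_td,
    n_tasks = dim(mg$X)[2], mu = mu
  )
  class(out) <- "dpca_decomposition"
  out
}

#' Variance report per demixed mode and per subspace
#'
#' Implements the per-component variance split into additive marginalization
#' contributions; subspace-level numbers are sums over same-label modes and
#' pie-chart totals are the marginalization totals.
#'
#' @param decomp `dpca_decomposition`.
#' @return list with `per_mode` data.frame, `subspace` (summed percentages
#'   per label), `subspace_share` (same, normalized to the explained total),
#'   `pie` marginalization totals, `residual_pct`.
#' @export
variance_table <- function(decomp) {
  vt <- decomp$variance_table
  ti_sum <- sum(vt$total_pct[vt$label == "task-independent"])
  td_sum <- sum(vt$total_pct[vt$label == "task-dependent"])
  list(
    per_mode = vt,
    subspace = c(`task-independent` = ti_sum, `task-dependent` = td_sum),
    subspace_share = c(
      `task-independent` = 100 * ti_sum / (ti_sum + td_sum),
      `task-dependent` = 100 * td_sum / (ti_sum + td_sum)
    ),
    pie = decomp$marginalization_totals,
    residual_pct = decomp$residual_pct
  )
}

#' Demixed projections of the trial-averaged activity
#'
#' @param decomp `dpca_decomposition`.
#' @param mode mode index.
#' @return tasks x 100 matrix: the per-task trajectories of that mode.
#' @export
dpca_projection <- function(decomp, mode) {
  z <- crossprod(decomp$decoder[, mode, drop = FALSE], unroll(decomp$X))
  matrix(z, nrow = decomp$n_tasks)
}

#' Leading-mode subspace of one label
#'
#' @param decomp `dpca_decomposition`.
#' @param label `"task-independent"` or `"task-dependent"`.
#' @param k number of leading modes (default 5).
#' @param strict error (naming the shortfall) if fewer than `k` modes carry
#'   that label.
#' @return `subspace` object (orthonormalized encoder axes).
#' @export
dpca_subspace <- function(decomp, label = c("task-independent",
                                            "task-dependent"),
                          k = 5, strict = TRUE) {
  label <- match.arg(label)
  idx <- which(decomp$variance_table$label == label)
  if (length(idx) < k) {
    if (strict) {
      stop("only ", length(idx), " ", label, " modes available, need ", k)
    }
    k <- length(idx)
  }
  idx <- idx[seq_len(k)]
  subspace(orthonormalize(decomp$encoder[, idx, drop = FALSE]),
           kind = label)
}

#' Remove leading demixed modes from activity
#'
#' `X <- X - sum_j f_j d_j^T X` over the top-`k` modes of the requested
#' label, applied to full-resolution activity (not only trial averages).
#'
#' @param rates channels x samples matrix (rows must match the channels the
#'   decomposition was fit on) or `rate_matrix`.
#' @param decomp `dpca_decomposition`.
#' @param which `"task-independent"` or `"task-dependent"`.
#' @param k number of leading modes of that label to remove; `k = 0` is the
#'   identity.
#' @return list with `rates` (reduced) and `removed_variance_fraction`
#'   measured on the input.
#' @export
remove_modes <- function(rates, decomp,
                         which = c("task-independent", "task-dependent"),
                         k) {
  which <- match.arg(which)
  if (inherits(rates, "rate_matrix")) {
    rates <- rates$rates[decomp$channels, , drop = FALSE]
  }
  stopifnot(nrow(rates) == nrow(decomp$decoder))
  if (k == 0) {
    return(list(rates = rates, removed_variance_fraction = 0,
                modes_removed = integer(0)))
  }
  idx <- base::which(decomp$variance_table$label == which)
  if (k > length(idx)) stop("k exceeds the number of ", which, " modes")
  idx <- idx[seq_len(k)]
  Xc <- rates - rowMeans(rates)
  out <- rates
  for (j in idx) {
    out <- out - decomp$encoder[, j, drop = FALSE] %*%
      crossprod(decomp$decoder[, j, drop = FALSE], out - rowMeans(out))
  }
  removed <- 1 - sum((out - rowMeans(out))^2) / sum(Xc^2)
  list(rates = out, removed_variance_fraction = removed, modes_removed = idx)
}
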