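#' Ridge regression of a target region on a source region with 10-fold CV
#'
#' Samples are the concatenated time-warped peri-gait signals of a single
#' task; cross-validation folds are contiguous blocks of whole gait cycles
#' so that temporal autocorrelation within a cycle never straddles a fold.
#' The regularizer is chosen by the one-standard-error rule: the largest
#' grid value whose mean held-out R2 is within one SE of the best mean R2.
#'
#' @param X samples x p source matrix (centered internally).
#' @param Y samples x q target matrix (centered internally).
#' @param lambda_grid ridge grid; default 20 log-spaced points spanning
#'   `1e-4` to `1e4` times the mean diagonal of `X^T X`.
#' @param n_folds folds (default 10).
#' @param cycle_len samples per gait cycle (default 100); folds are blocks
#'   of whole cycles.
#' @return object of class `comm_ridge`: `B_ridge` (p x q), `lambda_star`,
#'   `cv_curve` data.frame (lambda, mean R2, SE), centering means, `r2_full`
#'   (training R2 of the final fit), `n_samples`.
#' @export
fit_ridge_cv <- function(X, Y, lambda_grid = NULL, n_folds = 10,
                         cycle_len = 100) {
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  if (n < n_folds) stop("fewer samples than folds")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  XtX <- crossprod(Xc)
  lambda_grid <- lambda_grid %||%
    (mean(diag(XtX)) * 10^seq(-4, 4, length.out = 20))
  lambda_grid <- sort(lambda_grid)
  n_cyc <- max(1L, floor(n / cycle_len))
  n_folds <- min(n_folds, n_cyc)
  if (n_folds < 2) stop("need at least 2 cross-validation folds of whole cycles")
  fold_of_cycle <- cut(seq_len(n_cyc), breaks = n_folds, labels = FALSE)
  fold <- fold_of_cycle[pmin(ceiling(seq_len(n) / cycle_len), n_cyc)]
  XtY <- crossprod(Xc, Yc)
  r2 <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (f in seq_len(n_folds)) {
    te <- fold == f
    Xte <- Xc[te, , drop = FALSE]; Yte <- Yc[te, , drop = FALSE]
    G <- XtX - crossprod(Xte)
    H <- XtY - crossprod(Xte, Yte)
    sst <- sum(Yte^2)
    for (j in seq_along(lambda_grid)) {
      B <- solve(G + lambda_grid[j] * diag(ncol(Xc)), H)
      r2[f, j] <- 1 - sum((Yte - Xte %*% B)^2) / sst
    }
  }
  if (any(!is.finite(r2))) stop("non-finite cross-validated R2")
  mean_r2 <- colMeans(r2)
  se_r2 <- apply(r2, 2, stats::sd) / sqrt(n_folds)
  best <- which.max(mean_r2)
  ok <- mean_r2 >= mean_r2[best] - se_r2[best]
  lambda_star <- max(lambda_grid[ok])
  B <- solve(XtX + lambda_star * diag(ncol(Xc)), XtY)
  r2_full <- 1 - sum((Yc - Xc %*% B)^2) / sum(Yc^2)
  out <- list(
    B_ridge = B, lambda_star = lambda_star,
    cv_curve = data.frame(lambda = lambda_grid, mean_r2 = mean_r2,
                          se_r2 = se_r2),
    x_center = attr(Xc, "scaled:center"), y_center = attr(Yc, "scaled:center"),
    r2_full = r2_full, n_samples = n
  )
  class(out) <- "comm_ridge"
  out
}

#' Reduced-rank restriction of a ridge regression model
#'
#' `V` holds the principal components of the ridge prediction
#' `Yhat = X B_ridge`; `B_rrr(m) = B_ridge V_m V_m^T`. The retained rank
#' `m_rrr` is the smallest m whose prediction explains at least 95% of the
#' variance explained by the full ridge predictor. `Bbar = B_ridge V`; the
#' first `m_rrr` columns of `Bbar` span the communication subspace of the
#' source region.
#'
#' @param X,Y the matrices used for the ridge fit.
#' @param ridge `comm_ridge` fit.
#' @param level cumulative-variance level for rank selection (default 0.95).
#' @return object of class `comm_model`: `V` (q x q), `r2_curve`, `m_rrr`,
#'   `B_rrr` (at `m_rrr`), `Bbar`, `ridge`, orthonormal `basis` spanning the
#'   communication subspace in source-channel space.
#' @export
fit_rrr <- function(X, Y, ridge, level = 0.95) {
  Xc <- sweep(X, 2, ridge$x_center)
  Yc <- sweep(Y, 2, ridge$y_center)
  Yhat <- Xc %*% ridge$B_ridge
  V <- svd(Yhat, nu = 0)$v  # principal components of the ridge prediction
  sst <- sum(Yc^2)
  # SSE(m) telescopes over the ordered components: with T = Yhat V and
  # U = Y V, ||Y - Yhat V_m V_m^T||^2 = ||Y||^2 - sum_{j<=m} (2 U_j.T_j - ||T_j||^2)
  Tm <- Yhat %*% V
  Um <- Yc %*% V
  gain_j <- 2 * colSums(Um * Tm) - colSums(Tm^2)
  r2 <- cumsum(gain_j) / sst
  r2_ridge <- 1 - sum((Yc - Yhat)^2) / sst
  m_ok <- which(r2 >= level * r2_ridge)
  if (length(m_ok) == 0) stop("empty rank range")
  m_rrr <- min(m_ok)
  Bbar <- ridge$B_ridge %*% V
  out <- list(
    V = V, r2_curve = data.frame(m = seq_along(r2), r2 = r2),
    r2_ridge = r2_ridge, m_rrr = m_rrr,
    B_rrr = ridge$B_ridge %*% tcrossprod(V[, seq_len(m_rrr), drop = FALSE]),
    Bbar = Bbar, ridge = ridge,
    basis = communication_basis_from_bbar(Bbar, m_rrr)
  )
  class(out) <- "comm_model"
  out
}

communication_basis_from_bbar <- function(Bbar, m) {
  cols <- Bbar[, seq_len(m), drop = FALSE]
  Q <- orthonormalize(cols)
  if (ncol(Q) < m) {
    warning("rank-deficient Bbar columns; communication subspace reduced to ",
            ncol(Q), " dimensions")
  }
  Q
}

#' Communication subspace of a fitted model
#'
#' @param model `comm_model`.
#' @return `subspace` (kind "communication") spanned by the orthonormalized
#'   first `m_rrr` columns of `Bbar`.
#' @export
communication_basis <- function(model) {
  subspace(model$basis, kind = "communication")
}

#' Fit the full communication-subspace model for one task
#'
#' Convenience wrapper: builds the samples x channels matrices from two
#' peri-gait tensors (concatenated warped cycles of one task), runs the
#' ridge CV and the reduced-rank restriction.
#'
#' @param pt_source,pt_target `perigait_tensor`s of the source and target
#'   regions (same session: identical retained cycles).
#' @param task task index.
#' @param ... passed to [fit_ridge_cv()].
#' @return `comm_model`.
#' @export
fit_communication <- function(pt_source, pt_target, task, ...) {
  X <- t(tensor_to_matrix(pt_source, tasks = task))
  Y <- t(tensor_to_matrix(pt_target, tasks = task))
  ridge <- fit_ridge_cv(X, Y, ...)
  fit_rrr(X, Y, ridge)
}
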