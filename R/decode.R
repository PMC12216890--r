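#' Regularized linear discriminant analysis (rLDA)
#'
#' Shared-covariance Gaussian classifier with shrinkage of the pooled
#' covariance toward a scaled identity:
#' `S_reg = (1 - reg) * S + reg * (tr(S)/d) * I`.
#'
#' @param X n_obs x d feature matrix.
#' @param y class labels (coerced to factor).
#' @param reg shrinkage coefficient in `[0, 1]`.
#' @return object of class `rlda` with class means, regularized pooled
#'   covariance inverse, log-priors, classes.
#' @export
rlda_fit <- function(X, y, reg = 0.1) {
  y <- factor(y)
  X <- as.matrix(X)
  d <- ncol(X)
  classes <- levels(y)
  mus <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                  numeric(d)))
  S <- matrix(0, d, d)
  for (k in classes) {
    Xi <- X[y == k, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    S <- S + crossprod(Xi)
  }
  S <- S / (nrow(X) - length(classes))
  Sreg <- (1 - reg) * S + reg * (sum(diag(S)) / d) * diag(d)
  Sinv <- solve(Sreg)
  priors <- as.numeric(table(y)[classes]) / length(y)
  structure(list(means = mus, Sinv = Sinv, log_priors = log(priors),
                 classes = classes, reg = reg), class = "rlda")
}

#' Posterior class probabilities from an rLDA model
#' @param model `rlda`.
#' @param X n_obs x d matrix.
#' @return n_obs x n_classes matrix of posteriors (rows sum to 1).
#' @export
rlda_posterior <- function(model, X) {
  X <- as.matrix(X)
  A <- model$Sinv %*% t(model$means)              # d x K
  b <- -0.5 * colSums(t(model$means) * A) + model$log_priors
  disc <- X %*% A + rep(b, each = nrow(X))
  disc <- disc - apply(disc, 1, max)
  p <- exp(disc)
  p / rowSums(p)
}

#' Event-aligned neural feature vectors
#'
#' For each time `t`, per-channel rates are averaged in `B` equal bins over
#' the window `[t - L, t]` and concatenated.
#'
#' @param rates channels x samples matrix.
#' @param fs sampling rate (Hz).
#' @param times event times in seconds (all must be >= L).
#' @param L_ms window length in ms.
#' @param B number of bins (must divide the window into whole samples).
#' @return length(times) x (channels * B) matrix.
#' @export
event_features <- function(rates, fs, times, L_ms, B) {
  L <- round(L_ms / 1000 * fs)
  if (L %% B != 0) stop("window must split into an integral bin width")
  wb <- L / B
  n_ch <- nrow(rates)
  cum <- cbind(0, t(apply(rates, 1, cumsum)))  # n_ch x (T+1)
  ti <- round(times * fs)
  if (any(ti < L) || any(ti > ncol(rates))) {
    stop("event windows fall outside the recording")
  }
  out <- matrix(NA_real_, length(times), n_ch * B)
  for (j in seq_len(B)) {
    a <- ti - L + (j - 1) * wb
    b <- ti - L + j * wb
    out[, (j - 1) * n_ch + seq_len(n_ch)] <- t(cum[, b + 1] - cum[, a + 1]) / wb
  }
  out
}

#' Calibrate the gait-event decoder on one task
#'
#' Three classes: foot-strike, foot-off, and "none" exemplars taken at the
#' midpoints between consecutive events. Feature length `L`, bin count `B`,
#' and the rLDA regularization are chosen by cross-validation on the
#' calibration task (ties broken to smaller L, then smaller B, then larger
#' regularization); the final model is fit on the entire calibration task.
#'
#' @param rates channels x samples matrix (z-scored) or `rate_matrix`.
#' @param events `gait_events` table.
#' @param calibration_task task id used for calibration.
#' @param fs sampling rate if `rates` is a plain matrix.
#' @param L_grid window lengths in ms (default `c(100, 200, 300, 400, 500)`).
#' @param B_grid bin counts (default `c(5, 10)`).
#' @param reg_grid rLDA shrinkage grid (default `10^seq(-3, 0, length 4)`).
#' @param cv_folds folds for the grid search (default 5).
#' @param threshold posterior detection threshold (default 0.80).
#' @param refractory same-class detection dead time in seconds (default 0.1).
#' @return object of class `event_decoder`.
#' @export
fit_event_decoder <- function(rates, events, calibration_task, fs = NULL,
                              L_grid = c(100, 200, 300, 400, 500),
                              B_grid = c(5, 10),
                              reg_grid = 10^seq(-3, 0, length.out = 4),
                              cv_folds = 5, threshold = 0.80,
                              refractory = 0.1) {
  if (inherits(rates, "rate_matrix")) {
    fs <- rates$fs
    rates <- rates$rates
  }
  if (is.null(fs)) stop("fs required for a plain matrix")
  ex <- event_exemplars(events, calibration_task)
  if (min(table(ex$class)) < 10) stop("fewer than 10 events per class")
  Lmax <- max(L_grid)
  usable <- ex$time * fs >= Lmax & ex$time * fs <= ncol(rates)
  ex <- ex[usable, ]
  best <- NULL
  for (L in sort(L_grid)) {
    for (B in sort(B_grid)) {
      Xf <- event_features(rates, fs, ex$time, L, B)
      for (reg in sort(reg_grid)) {
        sc <- cv_macro_f(Xf, ex$class, reg, cv_folds)
        better <- is.null(best) || sc > best$score + 1e-12 ||
          (abs(sc - best$score) <= 1e-12 && reg > best$reg &&
             L == best$L && B == best$B)
        if (better) best <- list(L = L, B = B, reg = reg, score = sc)
      }
    }
  }
  Xf <- event_features(rates, fs, ex$time, best$L, best$B)
  model <- rlda_fit(Xf, ex$class, best$reg)
  dec <- structure(list(model = model, L = best$L, B = best$B, reg = best$reg,
                        cv_score = best$score, threshold = threshold,
                        refractory = refractory, fs = fs,
                        latency = c(strike = 0, off = 0),
                        calibration_task = calibration_task),
                   class = "event_decoder")
  # detection-latency calibration: threshold crossings fire on the rising
  # flank of the posterior, systematically ahead of the event; measure the
  # median lead per class on the calibration task and correct for it
  cal <- run_event_decoder(dec, rates, events, tasks = calibration_task)
  for (cls in c("strike", "off")) {
    d <- cal$detections[cal$detections$class == cls, , drop = FALSE]
    tru <- event_exemplars(events, calibration_task)
    tt <- tru$time[tru$class == cls]
    if (nrow(d) > 0) {
      offs <- vapply(d$time, function(t) {
        dt <- t - tt; dt[which.min(abs(dt))]
      }, numeric(1))
      dec$latency[cls] <- stats::median(offs)
    }
  }
  dec
}

event_exemplars <- function(events, task) {
  ev <- events[events$task_id == task, , drop = FALSE]
  if (nrow(ev) == 0) stop("calibration task absent from the event table")
  strikes <- sort(unique(c(ev$t_strike_start, ev$t_strike_end)))
  offs <- sort(ev$t_foot_off)
  stream <- rbind(data.frame(time = strikes, class = "strike"),
                  data.frame(time = offs, class = "off"))
  stream <- stream[order(stream$time), ]
  mid <- (stream$time[-1] + stream$time[-nrow(stream)]) / 2
  rbind(stream, data.frame(time = mid, class = "none"))
}

cv_macro_f <- function(Xf, y, reg, folds) {
  y <- factor(y)
  set.seed(7)  # fixed fold assignment so the grid search is deterministic
  fold <- sample(rep(seq_len(folds), length.out = length(y)))
  f_by_fold <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < nlevels(y)) return(NA_real_)
    m <- rlda_fit(Xf[tr, , drop = FALSE], y[tr], reg)
    p <- rlda_posterior(m, Xf[!tr, , drop = FALSE])
    pred <- m$classes[max.col(p)]
    macro_f_events(y[!tr], pred)
  }, numeric(1))
  mean(f_by_fold, na.rm = TRUE)
}

# harmonic-mean F per event class (strike, off), averaged
macro_f_events <- function(true, pred) {
  fs <- vapply(c("strike", "off"), function(k) {
    tp <- sum(pred == k & true == k)
    prec <- if (sum(pred == k) == 0) 0 else tp / sum(pred == k)
    rec <- if (sum(true == k) == 0) 0 else tp / sum(true == k)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(fs)
}

#' Run the gait-event decoder and score detections
#'
#' Posteriors are evaluated on a sliding grid (default every 10 ms); a
#' detection fires on an upward crossing of the threshold, same-class
#' detections within the refractory period are suppressed, and each
#' detection is matched to the nearest unmatched true event of the same
#' class within `match_tol` seconds.
#'
#' @param decoder `event_decoder`.
#' @param rates channels x samples matrix (same channel set as training).
#' @param events `gait_events` with the true events of the evaluated task(s).
#' @param tasks task ids to evaluate (default all in `events`).
#' @param step posterior evaluation step in seconds (default 0.01).
#' @param match_tol detection-matching tolerance in seconds (default 0.125).
#' @return list with `f_score`, `per_class` data.frame
#'   (precision/recall/F), `detections` data.frame.
#' @export
run_event_decoder <- function(decoder, rates, events, tasks = NULL,
                              step = 0.01, match_tol = 0.125) {
  if (inherits(rates, "rate_matrix")) rates <- rates$rates
  fs <- decoder$fs
  tasks <- tasks %||% unique(events$task_id)
  det_all <- list()
  truth_all <- list()
  for (tk in tasks) {
    ev <- events[events$task_id == tk, , drop = FALSE]
    t0 <- min(ev$t_strike_start); t1 <- max(ev$t_strike_end)
    t0 <- max(t0, decoder$L / 1000)
    grid <- seq(t0, min(t1, (ncol(rates) - 1) / fs), by = step)
    Xf <- event_features(rates, fs, grid, decoder$L, decoder$B)
    post <- rlda_posterior(decoder$model, Xf)
    colnames(post) <- decoder$model$classes
    for (cls in c("strike", "off")) {
      p <- post[, cls]
      up <- which(p[-1] >= decoder$threshold & p[-length(p)] < decoder$threshold) + 1
      tdet <- grid[up]
      keep <- logical(length(tdet))
      last <- -Inf
      for (i in seq_along(tdet)) {
        if (tdet[i] - last >= decoder$refractory) {
          keep[i] <- TRUE; last <- tdet[i]
        }
      }
      tk_times <- tdet[keep] - decoder$latency[[cls]]
      det_all[[paste(tk, cls)]] <- data.frame(
        task_id = rep(tk, length(tk_times)),
        class = rep(cls, length(tk_times)),
        time = tk_times)
    }
    truth_all[[as.character(tk)]] <- data.frame(
      task_id = tk,
      class = rep(c("strike", "off"),
                  c(length(unique(c(ev$t_strike_start, ev$t_strike_end))),
                    nrow(ev))),
      time = c(sort(unique(c(ev$t_strike_start, ev$t_strike_end))),
               sort(ev$t_foot_off))
    )
  }
  det <- do.call(rbind, det_all)
  tru <- do.call(rbind, truth_all)
  per_class <- do.call(rbind, lapply(c("strike", "off"), function(cls) {
    d <- det[det$class == cls, , drop = FALSE]
    g <- tru[tru$class == cls, , drop = FALSE]
    matched_true <- rep(FALSE, nrow(g))
    hit <- 0
    for (i in seq_len(nrow(d))) {
      dt <- abs(g$time - d$time[i])
      dt[matched_true | g$task_id != d$task_id[i]] <- Inf
      j <- which.min(dt)
      if (length(j) == 1 && dt[j] <= match_tol) {
        matched_true[j] <- TRUE; hit <- hit + 1
      }
    }
    prec <- if (nrow(d) == 0) 0 else hit / nrow(d)
    rec <- if (nrow(g) == 0) 0 else hit / nrow(g)
    f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cls, precision = prec, recall = rec, f = f,
               n_detections = nrow(d), n_true = nrow(g))
  }))
  list(f_score = mean(per_class$f), per_class = per_class, detections = det)
}

#' Task classification from per-cycle behavioral features
#'
#' rLDA with 5-fold cross-validation; reports the mean held-out accuracy
#' and the pooled confusion matrix (rows = true task, so rows sum to the
#' per-task trial counts).
#'
#' @param features n_cycles x d matrix (one row per gait cycle).
#' @param labels task labels per cycle.
#' @param reg rLDA shrinkage (default 0.1).
#' @param folds CV folds (default 5).
#' @param seed fold-assignment seed.
#' @return list with `accuracy`, `confusion`, `fold_accuracy`.
#' @export
classify_task <- function(features, labels, reg = 0.1, folds = 5, seed = 1) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 tasks")
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = length(labels)))
  conf <- matrix(0L, nlevels(labels), nlevels(labels),
                 dimnames = list(true = levels(labels),
                                 predicted = levels(labels)))
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < nlevels(labels)) {
      stop("a task is absent from a training fold")
    }
    m <- rlda_fit(features[tr, , drop = FALSE], labels[tr], reg)
    pred <- m$classes[max.col(rlda_posterior(m, features[!tr, , drop = FALSE]))]
    acc[f] <- mean(pred == labels[!tr])
    tt <- table(factor(labels[!tr], levels(labels)),
                factor(pred, levels(labels)))
    conf <- conf + as.matrix(tt)
  }
  list(accuracy = mean(acc), confusion = conf, fold_accuracy = acc)
}

#' Wiener (linear filter) reconstruction of EMG / kinematic time series
#'
#' Per output, a linear filter over lagged population rates spanning the
#' window (10 ms lag spacing); the ridge regularizer is chosen by k-fold CV
#' on the calibration samples, the filter is fit on all calibration
#' samples, and performance is reported on each test set as
#' `R2 = 1 - Var(err) / Var(target)`. An optional static polynomial stage
#' (cascade) can follow the linear filter.
#'
#' @param rates channels x samples matrix.
#' @param targets n_outputs x samples matrix aligned with `rates`.
#' @param fs sampling rate (Hz).
#' @param window_ms filter window (100 for EMG, 300 for kinematics).
#' @param calibration_idx sample indices (columns) of the calibration task.
#' @param test_idx list of sample-index vectors to evaluate on.
#' @param lambda_grid ridge grid (default log-spaced around the data scale).
#' @param folds CV folds for lambda (default 5).
#' @param poly_degree static-stage degree (default 1 = purely linear).
#' @param lag_step_ms lag spacing (default 10).
#' @return list with `weights`, `lambda`, `r2` (test-set x output matrix),
#'   `predict` function.
#' @export
fit_apply_wiener <- function(rates, targets, fs, window_ms,
                             calibration_idx, test_idx = list(),
                             lambda_grid = NULL, folds = 5,
                             poly_degree = 1, lag_step_ms = 10) {
  lag_step <- round(lag_step_ms / 1000 * fs)
  if (lag_step < 1) stop("window shorter than one lag step")
  lags <- seq(0, round(window_ms / 1000 * fs), by = lag_step)
  build <- function(idx) {
    idx <- idx[idx > max(lags)]
    X <- do.call(cbind, lapply(lags, function(l) t(rates[, idx - l, drop = FALSE])))
    list(X = cbind(1, X), idx = idx)
  }
  cal <- build(calibration_idx)
  Ycal <- t(targets[, cal$idx, drop = FALSE])
  XtX <- crossprod(cal$X)
  lambda_grid <- lambda_grid %||%
    (mean(diag(XtX)) * 10^seq(-6, 2, length.out = 9))
  set.seed(11)
  fold <- sample(rep(seq_len(folds), length.out = nrow(cal$X)))
  cv <- vapply(lambda_grid, function(lam) {
    err <- 0; tot <- 0
    for (f in seq_len(folds)) {
      tr <- fold != f
      W <- solve(crossprod(cal$X[tr, , drop = FALSE]) + lam * diag(ncol(cal$X)),
                 crossprod(cal$X[tr, , drop = FALSE], Ycal[tr, , drop = FALSE]))
      pr <- cal$X[!tr, , drop = FALSE] %*% W
      err <- err + sum((Ycal[!tr, , drop = FALSE] - pr)^2)
      tot <- tot + sum(scale(Ycal[!tr, , drop = FALSE], scale = FALSE)^2)
    }
    1 - err / tot
  }, numeric(1))
  lambda <- lambda_grid[which.max(cv)]
  W <- solve(XtX + lambda * diag(ncol(cal$X)), crossprod(cal$X, Ycal))
  lin_cal <- cal$X %*% W
  poly_fit <- NULL
  if (poly_degree > 1) {
    poly_fit <- lapply(seq_len(ncol(Ycal)), function(j) {
      stats::lm(Ycal[, j] ~ stats::poly(lin_cal[, j], poly_degree, raw = TRUE))
    })
  }
  predict_fun <- function(idx) {
    b <- build(idx)
    pr <- b$X %*% W
    if (!is.null(poly_fit)) {
      for (j in seq_len(ncol(pr))) {
        pr[, j] <- stats::predict(poly_fit[[j]],
          newdata = data.frame(stats::poly(pr[, j], poly_degree, raw = TRUE)))
      }
    }
    list(pred = pr, idx = b$idx)
  }
  r2 <- NULL
  if (length(test_idx) > 0) {
    r2 <- t(vapply(test_idx, function(idx) {
      p <- predict_fun(idx)
      Yt <- t(targets[, p$idx, drop = FALSE])
      1 - colSums((Yt - p$pred)^2) /
        colSums(sweep(Yt, 2, colMeans(Yt))^2)
    }, numeric(nrow(targets))))
  }
  list(weights = W, lambda = lambda, r2 = r2, predict = predict_fun,
       lags = lags, window_ms = window_ms, poly_degree = poly_degree)
}

#' Savitzky-Golay velocity estimate from positions
#'
#' First-derivative Savitzky-Golay filtering (exact for polynomial inputs
#' up to the fitting order at interior samples).
#'
#' @param positions numeric vector or rows-as-channels matrix, uniformly
#'   sampled.
#' @param window filter length in samples (odd, > polyorder).
#' @param polyorder fitting polynomial order.
#' @param fs sampling rate (Hz).
#' @return velocities, same shape as `positions`.
#' @export
savgol_velocity <- function(positions, window = 31, polyorder = 3,
                            fs = 1000) {
  if (window %% 2 == 0 || window <= polyorder) {
    stop("window must be odd and greater than polyorder")
  }
  f <- function(x) signal::sgolayfilt(x, p = polyorder, n = window, m = 1,
                                      ts = 1 / fs)
  if (is.matrix(positions)) t(apply(positions, 1, f)) else f(positions)
}
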