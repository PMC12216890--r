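#' Gait-event table constructor and validator
#'
#' One row per gait cycle: the epoch between two consecutive foot strikes,
#' with the intervening foot-off marking the stance/swing boundary.
#'
#' @param task_id integer or factor task labels.
#' @param cycle_index integer cycle index within task.
#' @param t_strike_start,t_foot_off,t_strike_end event times in seconds.
#' @return data.frame of class `gait_events`.
#' @export
gait_event_table <- function(task_id, cycle_index, t_strike_start,
                             t_foot_off, t_strike_end) {
  ev <- data.frame(
    task_id = task_id, cycle_index = cycle_index,
    t_strike_start = t_strike_start, t_foot_off = t_foot_off,
    t_strike_end = t_strike_end
  )
  bad <- which(!(ev$t_strike_start < ev$t_foot_off &
                   ev$t_foot_off < ev$t_strike_end))
  if (length(bad) > 0) {
    stop("invalid event ordering (need strike_start < foot_off < strike_end) in row(s): ",
         paste(bad, collapse = ", "))
  }
  class(ev) <- c("gait_events", "data.frame")
  ev
}

#' Estimate smoothed, z-scored firing rates from spike times
#'
#' Spikes are counted in sliding 10 ms bins stepped at 0.5 ms (2000 Hz),
#' scaled to Hz, convolved with a Gaussian kernel (50 ms s.d.), z-scored
#' per channel over the session, and decimated to 1000 Hz by taking every
#' second sample (the smoothing already bandlimits the signal).
#'
#' @param spike_times list of numeric vectors, one per channel, spike times
#'   in seconds within `[0, span]`.
#' @param span session duration in seconds (>= 1).
#' @param zscore z-score per channel (default TRUE). Channels with zero
#'   variance are flagged and left un-divided.
#' @return object of class `rate_matrix`: list with `rates`
#'   (channels x samples at 1000 Hz), `fs = 1000`, `constant_channels`,
#'   `zscored`.
#' @export
estimate_rates <- function(spike_times, span, zscore = TRUE) {
  stopifnot(is.list(spike_times), span >= 1)
  n_hi <- floor(span * 2000)
  bin_w <- 20L  # 10 ms window = 20 half-ms steps
  kern <- gaussian_kernel(sd_samples = 0.05 * 2000)
  rates <- t(vapply(spike_times, function(st) {
    if (length(st) > 0 && (any(st < 0) || any(st > span))) {
      stop("spike times outside the session span")
    }
    cnt <- sliding_count(st, n_hi, bin_w)
    smooth_conv(cnt / 0.01, kern)  # counts per 10 ms -> Hz, then smooth
  }, numeric(n_hi)))
  rates <- rates[, seq(1, n_hi, by = 2), drop = FALSE]  # decimate to 1 kHz
  rates <- rates[, seq_len(floor(span * 1000)), drop = FALSE]
  out <- list(rates = rates, fs = 1000, zscored = FALSE,
              constant_channels = integer(0))
  class(out) <- "rate_matrix"
  if (zscore) out <- zscore_rates(out)
  out
}

# spike counts in sliding [t - 10 ms, t] windows on the 0.5 ms grid
sliding_count <- function(st, n_hi, bin_w) {
  cnt <- numeric(n_hi)
  if (length(st) == 0) return(cnt)
  idx <- pmin(pmax(floor(st * 2000) + 1, 1), n_hi)
  base <- tabulate(idx, nbins = n_hi)
  out <- as.numeric(stats::filter(base, rep(1, bin_w), sides = 1))
  out[seq_len(bin_w - 1)] <- cumsum(base)[seq_len(bin_w - 1)]  # partial windows
  out
}

gaussian_kernel <- function(sd_samples, half_width = 4) {
  x <- seq(-ceiling(half_width * sd_samples), ceiling(half_width * sd_samples))
  k <- exp(-x^2 / (2 * sd_samples^2))
  k / sum(k)
}

# centered convolution with edge renormalization
smooth_conv <- function(x, kern) {
  n <- length(x)
  half <- (length(kern) - 1) / 2
  xp <- c(rep(0, half), x, rep(0, half))
  num <- stats::convolve(xp, rev(kern), type = "filter")
  wp <- c(rep(0, half), rep(1, n), rep(0, half))
  den <- stats::convolve(wp, rev(kern), type = "filter")
  num / den
}

#' Z-score a rate matrix per channel over the session
#'
#' Idempotent; channels with zero variance are flagged as constant, centered
#' but not divided, and excluded from downstream analyses.
#'
#' @param x `rate_matrix` or plain channels x samples matrix.
#' @param fs sampling rate, required if `x` is a plain matrix.
#' @return `rate_matrix` with `zscored = TRUE`.
#' @export
zscore_rates <- function(x, fs = NULL) {
  if (is.matrix(x)) {
    if (is.null(fs)) stop("fs required for a plain matrix")
    x <- structure(list(rates = x, fs = fs, zscored = FALSE,
                        constant_channels = integer(0)),
                   class = "rate_matrix")
  }
  mu <- rowMeans(x$rates)
  ctr <- x$rates - mu
  sdv <- sqrt(rowMeans(ctr^2))
  const <- which(sdv < 1e-12)
  sdv[const] <- 1
  x$rates <- ctr / sdv
  x$constant_channels <- sort(union(x$constant_channels, const))
  x$zscored <- TRUE
  x
}

#' Segment rates into gait cycles and time-warp to a 100-sample phase grid
#'
#' Cycles longer than 1.5 s are rejected; cycles whose stance duration lies
#' outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (computed per task over the
#' duration-surviving cycles) are rejected. Each surviving cycle's stance is
#' linearly resampled to samples 0-59 and its swing to samples 60-99.
#'
#' @param rates `rate_matrix` (or plain matrix with `fs`).
#' @param events `gait_events` table.
#' @param fs sampling rate if `rates` is a plain matrix.
#' @param max_duration cycle rejection threshold in seconds (default 1.5).
#' @return object of class `perigait_tensor`: list with `tensor`
#'   (channels x tasks x cycles x 100, NA-padded), `trial_avg`
#'   (channels x tasks x 100), `tasks`, `n_cycles` per task, `rejections`
#'   data.frame, `events_kept`.
#' @export
segment_and_warp <- function(rates, events, fs = NULL, max_duration = 1.5) {
  if (is.matrix(rates)) {
    if (is.null(fs)) stop("fs required for a plain matrix")
    rates <- structure(list(rates = rates, fs = fs, zscored = FALSE,
                            constant_channels = integer(0)),
                       class = "rate_matrix")
  }
  stopifnot(inherits(events, "gait_events"))
  tasks <- sort(unique(events$task_id))
  rej <- data.frame(task_id = events$task_id[0], cycle_index = integer(0),
                    reason = character(0))
  keep_rows <- list()
  for (tk in tasks) {
    ev <- events[events$task_id == tk, , drop = FALSE]
    dur <- ev$t_strike_end - ev$t_strike_start
    long <- dur > max_duration
    if (any(long)) {
      rej <- rbind(rej, data.frame(task_id = tk,
                                   cycle_index = ev$cycle_index[long],
                                   reason = "duration"))
    }
    ev <- ev[!long, , drop = FALSE]
    stance <- ev$t_foot_off - ev$t_strike_start
    q <- stats::quantile(stance, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    out <- stance < q[1] - 1.5 * iqr | stance > q[2] + 1.5 * iqr
    if (any(out)) {
      rej <- rbind(rej, data.frame(task_id = tk,
                                   cycle_index = ev$cycle_index[out],
                                   reason = "stance_iqr"))
    }
    ev <- ev[!out, , drop = FALSE]
    if (nrow(ev) < 3) {
      stop("fewer than 3 surviving gait cycles in task ", tk)
    }
    keep_rows[[as.character(tk)]] <- ev
  }
  n_ch <- nrow(rates$rates)
  n_samp <- ncol(rates$rates)
  max_cyc <- max(vapply(keep_rows, nrow, integer(1)))
  tensor <- array(NA_real_, c(n_ch, length(tasks), max_cyc, 100))
  tgrid <- (seq_len(n_samp) - 1) / rates$fs
  for (ti in seq_along(tasks)) {
    ev <- keep_rows[[as.character(tasks[ti])]]
    for (ci in seq_len(nrow(ev))) {
      tt <- warp_sample_times(ev$t_strike_start[ci], ev$t_foot_off[ci],
                              ev$t_strike_end[ci])
      idx <- tt * rates$fs + 1  # fractional sample index
      lo <- pmin(pmax(floor(idx), 1), n_samp)
      hi <- pmin(lo + 1, n_samp)
      w <- idx - lo
      tensor[, ti, ci, ] <- rates$rates[, lo, drop = FALSE] * rep(1 - w, each = n_ch) +
        rates$rates[, hi, drop = FALSE] * rep(w, each = n_ch)
    }
  }
  trial_avg <- trial_average(tensor)
  out <- list(
    tensor = tensor, trial_avg = trial_avg, tasks = tasks,
    n_cycles = vapply(keep_rows, nrow, integer(1)),
    rejections = rej,
    events_kept = do.call(rbind, keep_rows),
    constant_channels = rates$constant_channels
  )
  class(out) <- "perigait_tensor"
  out
}

# mean over the cycle axis of a channels x tasks x cycles x 100 tensor
trial_average <- function(tensor) {
  colMeans(aperm(tensor, c(3, 1, 2, 4)), na.rm = TRUE, dims = 1)
}

# phase p in 0..59 spans the stance, 60..99 the swing (half-open intervals)
warp_sample_times <- function(t0, t_off, t1) {
  p <- 0:99
  st <- t0 + (p[p < 60] / 60) * (t_off - t0)
  sw <- t_off + ((p[p >= 60] - 60) / 40) * (t1 - t_off)
  c(st, sw)
}

#' Per-channel peri-gait statistics
#'
#' Computes, per channel: mean rate and modulation depth (max minus min of
#' the trial-averaged peri-gait rate, per task), the preferred gait phase
#' (PGP, circular argmax of the trial average, ties to the smallest index),
#' the circular standard deviation of the PGP across tasks, and the
#' population cross-task correlation: Pearson R over all cycle pairs,
#' averaged over pairs, then task combinations, then channels (self-pairs
#' excluded from same-task combinations; the population value averages the
#' cross-task combinations only).
#'
#' @param pt `perigait_tensor`.
#' @param sd_form circular s.d. convention, `"angular"` or `"log"`.
#' @return list with `per_channel` data.frame, `combo_table`
#'   (channel-averaged R per task pair), `population_cross_task_correlation`,
#'   `pgp_sd_mean` (mean across non-constant channels, degrees).
#' @export
perigait_stats <- function(pt, sd_form = c("angular", "log")) {
  sd_form <- match.arg(sd_form)
  stopifnot(inherits(pt, "perigait_tensor"))
  n_ch <- dim(pt$tensor)[1]
  n_task <- dim(pt$tensor)[2]
  if (n_task < 2) stop("need >= 2 tasks for cross-task statistics")
  const <- pt$constant_channels %||% integer(0)

  pgp <- matrix(NA_integer_, n_ch, n_task)
  mdepth <- matrix(NA_real_, n_ch, n_task)
  mrate <- matrix(NA_real_, n_ch, n_task)
  for (ti in seq_len(n_task)) {
    avg <- pt$trial_avg[, ti, , drop = FALSE]
    for (ch in seq_len(n_ch)) {
      v <- avg[ch, 1, ]
      mrate[ch, ti] <- mean(v)
      mdepth[ch, ti] <- max(v) - min(v)
      if (max(v) - min(v) > 1e-12) pgp[ch, ti] <- which.max(v) - 1L
    }
  }
  pgp_sd <- vapply(seq_len(n_ch), function(ch) {
    ph <- pgp[ch, ]
    if (anyNA(ph)) return(NA_real_)
    circ_sd(phase_to_rad(ph), form = sd_form)
  }, numeric(1))
  pgp_sd[const] <- NA_real_

  combos <- utils::combn(n_task, 2)
  combo_R <- matrix(NA_real_, n_ch, ncol(combos) + n_task)
  cross_cols <- seq_len(ncol(combos))
  for (k in seq_len(ncol(combos))) {
    a <- combos[1, k]; b <- combos[2, k]
    for (ch in seq_len(n_ch)) {
      combo_R[ch, k] <- mean_pair_correlation(pt, ch, a, b)
    }
  }
  for (a in seq_len(n_task)) {
    for (ch in seq_len(n_ch)) {
      combo_R[ch, ncol(combos) + a] <- mean_pair_correlation(pt, ch, a, a)
    }
  }
  ok <- setdiff(seq_len(n_ch), const)
  combo_means <- colMeans(combo_R[ok, , drop = FALSE], na.rm = TRUE)
  pop_R <- mean(combo_means[cross_cols])

  list(
    per_channel = data.frame(
      channel = seq_len(n_ch),
      mean_rate = rowMeans(mrate),
      modulation_depth = rowMeans(mdepth),
      pgp_sd_deg = pgp_sd
    ),
    pgp = pgp,
    combo_table = data.frame(
      task_a = c(combos[1, ], seq_len(n_task)),
      task_b = c(combos[2, ], seq_len(n_task)),
      mean_R = combo_means
    ),
    population_cross_task_correlation = pop_R,
    pgp_sd_mean = mean(pgp_sd[ok], na.rm = TRUE)
  )
}

# mean Pearson R over all cycle pairs of (task a, task b) for one channel
mean_pair_correlation <- function(pt, ch, a, b) {
  A <- pt$tensor[ch, a, seq_len(pt$n_cycles[a]), , drop = TRUE]
  B <- pt$tensor[ch, b, seq_len(pt$n_cycles[b]), , drop = TRUE]
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  sa <- apply(A, 1, stats::sd); sb <- apply(B, 1, stats::sd)
  A <- A[sa > 1e-12, , drop = FALSE]; B <- B[sb > 1e-12, , drop = FALSE]
  if (nrow(A) == 0 || nrow(B) == 0) return(NA_real_)
  R <- stats::cor(t(A), t(B))
  if (a == b) {
    diag(R) <- NA
  }
  mean(R, na.rm = TRUE)
}
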