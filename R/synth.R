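#' Configuration for the synthetic session generator
#'
#' Defaults describe the recording regime the package targets: five
#' locomotor tasks, 48-channel regions, ~100 retained gait cycles per task
#' with ~0.94 s mean duration, gait-phase-locked firing built from a small
#' number of task-independent (TI) and task-dependent (TD) latents with a
#' configurable TI variance fraction.
#'
#' @param n_tasks number of tasks (default 5).
#' @param cycles_per_task gait cycles per task (default 100).
#' @param n_channels channels in the generated region (default 48).
#' @param n_ti_latents,n_td_latents latent counts (default 6 each).
#' @param ti_variance_fraction fraction of signal variance carried by the
#'   TI latents (default 0.68).
#' @param harmonic_order maximum Fourier harmonic of the latent curves
#'   (default 9; must satisfy `2 * harmonic_order >= n_ti_latents +
#'   n_td_latents` so the planted latent sets span independent directions
#'   of the periodic function space).
#' @param baseline_rate baseline firing rate, Hz (default 20).
#' @param gain Hz of rate change per latent unit (default 5).
#' @param noise_sd white-noise s.d. in rate units (default 1).
#' @param cycle_duration_mean,cycle_duration_sd seconds (defaults 0.94,
#'   0.10); durations are truncated to (0.3, 1.5).
#' @param stance_fraction_mean,stance_fraction_sd stance fraction of the
#'   cycle (defaults 0.60, 0.025), truncated to (0.2, 0.8).
#' @param comm_rank rank of a planted inter-region map (default 3).
#' @param comm_alignment alpha in `[0, 1]`: 1 = the planted map reads only
#'   TI latents, 0 = only TD latents (default 1).
#' @param spike_mode `"rates_only"` (default) or `"poisson"`.
#' @param fs sampling rate of the emitted record, Hz (default 1000).
#' @param task_gap gap between task blocks, seconds (default 1).
#' @param seed integer RNG seed (default 1).
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_tasks = 5, cycles_per_task = 100, n_channels = 48,
                         n_ti_latents = 6, n_td_latents = 6,
                         ti_variance_fraction = 0.68, harmonic_order = 9,
                         baseline_rate = 20, gain = 5, noise_sd = 1,
                         cycle_duration_mean = 0.94, cycle_duration_sd = 0.10,
                         stance_fraction_mean = 0.60,
                         stance_fraction_sd = 0.025,
                         comm_rank = 3, comm_alignment = 1,
                         spike_mode = c("rates_only", "poisson"),
                         fs = 1000, task_gap = 1, seed = 1) {
  spike_mode <- match.arg(spike_mode)
  cfg <- as.list(environment())
  counts <- c(n_tasks, cycles_per_task, n_channels, n_ti_latents,
              n_td_latents, comm_rank)
  if (any(counts < 1)) stop("all counts must be positive")
  if (n_ti_latents + n_td_latents > n_channels) {
    stop("n_ti_latents + n_td_latents must not exceed n_channels")
  }
  if (ti_variance_fraction < 0 || ti_variance_fraction > 1) {
    stop("ti_variance_fraction must lie in [0, 1]")
  }
  if (comm_alignment < 0 || comm_alignment > 1) {
    stop("comm_alignment must lie in [0, 1]")
  }
  if (stance_fraction_mean <= 0.2 || stance_fraction_mean >= 0.8) {
    stop("degenerate stance fraction (must lie inside (0.2, 0.8))")
  }
  if (2 * harmonic_order < n_ti_latents + n_td_latents) {
    stop("harmonic_order too small: need 2 * harmonic_order >= ",
         "n_ti_latents + n_td_latents for independent latent curves")
  }
  class(cfg) <- "synth_config"
  cfg
}

# random smooth periodic curve on the 100-sample phase grid, zero-mean
fourier_curve <- function(harmonics) {
  p <- 0:99
  v <- numeric(100)
  for (h in seq_len(harmonics)) {
    v <- v + stats::rnorm(1, sd = 1 / h) * cos(2 * pi * h * p / 100) +
      stats::rnorm(1, sd = 1 / h) * sin(2 * pi * h * p / 100)
  }
  v - mean(v)
}

# orthonormalize columns then rescale each to unit RMS
orthonormal_unit_rms <- function(M) {
  Q <- qr.Q(qr(M))
  Q * sqrt(nrow(M))
}

# Channel loadings with mutually orthonormal columns and, when both block
# sizes are even, equal per-channel power in each block: columns come in
# cos/sin pairs at distinct spatial frequencies (cos^2 + sin^2 = const per
# row), with a random rotation inside each block. Equal per-channel power
# makes the planted variance split invariant to per-channel z-scoring.
channel_loadings <- function(n_ch, n_ti, n_td) {
  if (n_ti %% 2 == 0 && n_td %% 2 == 0 &&
      (n_ti + n_td) / 2 <= floor((n_ch - 1) / 2)) {
    freqs <- sample(seq_len(floor((n_ch - 1) / 2)), (n_ti + n_td) / 2)
    ch <- 0:(n_ch - 1)
    cols <- lapply(freqs, function(fq) {
      phi <- stats::runif(1, 0, 2 * pi)
      cbind(cos(2 * pi * fq * ch / n_ch + phi),
            sin(2 * pi * fq * ch / n_ch + phi)) * sqrt(2 / n_ch)
    })
    W <- do.call(cbind, cols)
    rot <- function(k) qr.Q(qr(matrix(stats::rnorm(k * k), k)))
    W[, seq_len(n_ti)] <- W[, seq_len(n_ti), drop = FALSE] %*% rot(n_ti)
    W[, n_ti + seq_len(n_td)] <-
      W[, n_ti + seq_len(n_td), drop = FALSE] %*% rot(n_td)
    W
  } else {
    # odd block sizes: generic random orthonormal loadings (per-channel
    # power then varies, so z-scoring can shift the realized split slightly)
    orthonormalize(matrix(stats::rnorm(n_ch * (n_ti + n_td)), n_ch))
  }
}

#' Generate a synthetic single-region session with planted latent structure
#'
#' The emitted rate (or spike) record is built as
#' `baseline + gain * W %*% z + noise`, where `z` stacks TI latents (one
#' smooth periodic curve per latent, identical across tasks) and TD latents
#' (per-task curves with zero across-task mean), and `W` holds mutually
#' orthonormal channel loadings. Latent amplitudes are rescaled analytically
#' so the TI fraction of the noiseless signal variance equals
#' `ti_variance_fraction` exactly. Cycle durations and stance fractions are
#' jittered per cycle before any warping. Deterministic given
#' `config$seed`.
#'
#' @param config `synth_config`.
#' @return list with `session` (class `session_container`: `regions$source`
#'   record, `events`, `config`) and `truth` (class `synth_truth`: planted
#'   bases, latent curves on the phase grid, amplitudes, variance
#'   fractions, full-resolution latent time series, event table, seed).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_ti <- config$n_ti_latents; n_td <- config$n_td_latents
  n_task <- config$n_tasks

  # TI curves: orthonormal on the grid, unit RMS. Their task-concatenations
  # are automatically orthogonal to any task-demeaned (TD) concatenation.
  ti_raw <- vapply(seq_len(n_ti), function(i) fourier_curve(config$harmonic_order),
                   numeric(100))
  ti_curves <- orthonormal_unit_rms(ti_raw)  # 100 x n_ti

  # TD curves: task-profile x curve tensor construction,
  #   g_k(task, phase) = sum_j u_j[task] * psi_{k,j}(phase),
  # with J task profiles u_j orthonormal over tasks and orthogonal to the
  # all-ones vector (zero across-task mean), and n_td * J curves psi
  # mutually orthonormal and orthogonal to the TI curves. This makes the
  # TD set exactly orthogonal with equal power WITHIN every task (so any
  # mixture of TD latents has the same per-task power profile, keeping
  # single-task statistics well conditioned) while the task-concatenations
  # are exactly orthonormal, so the planted variance split is additive.
  J <- max(1L, min(n_task - 1L,
                   floor((2 * config$harmonic_order - n_ti) / n_td)))
  U_task <- matrix(stats::rnorm(n_task * J), n_task)
  U_task <- sweep(U_task, 2, colMeans(U_task))
  U_task <- qr.Q(qr(U_task))[, seq_len(J), drop = FALSE]
  psi_raw <- vapply(seq_len(n_td * J), function(i) {
    g <- fourier_curve(config$harmonic_order)
    g - ti_curves %*% (crossprod(ti_curves, g) / 100)
  }, numeric(100))
  psi <- orthonormal_unit_rms(psi_raw)       # 100 x (n_td * J)
  td_curves <- array(0, c(100, n_task, n_td))
  for (k in seq_len(n_td)) {
    for (j in seq_len(J)) {
      td_curves[, , k] <- td_curves[, , k] +
        outer(psi[, (k - 1) * J + j], U_task[, j])
    }
  }
  td_curves <- td_curves * sqrt(n_task / J)  # unit RMS over the concatenation

  W <- channel_loadings(config$n_channels, n_ti, n_td)
  ti_basis <- W[, seq_len(n_ti), drop = FALSE]
  td_basis <- W[, n_ti + seq_len(n_td), drop = FALSE]

  f <- config$ti_variance_fraction
  amp_ti <- rep(sqrt(config$n_channels * f / n_ti), n_ti)
  amp_td <- rep(sqrt(config$n_channels * (1 - f) / n_td), n_td)

  events <- synth_events(config)
  span <- max(events$t_strike_end) + config$task_gap
  n_samp <- floor(span * config$fs)
  tgrid <- (seq_len(n_samp) - 1) / config$fs

  Z <- matrix(0, n_ti + n_td, n_samp)  # latent time series (amplitude-scaled)
  for (ti_row in seq_len(nrow(events))) {
    ev <- events[ti_row, ]
    i0 <- floor(ev$t_strike_start * config$fs) + 1
    i1 <- min(floor(ev$t_strike_end * config$fs), n_samp)
    if (i1 < i0) next
    tt <- tgrid[i0:i1]
    ph <- cycle_phase(tt, ev$t_strike_start, ev$t_foot_off, ev$t_strike_end)
    tk <- match(ev$task_id, sort(unique(events$task_id)))
    for (k in seq_len(n_ti)) {
      Z[k, i0:i1] <- amp_ti[k] * interp_circular(ti_curves[, k], ph)
    }
    for (k in seq_len(n_td)) {
      Z[n_ti + k, i0:i1] <- amp_td[k] * interp_circular(td_curves[, tk, k], ph)
    }
  }
  rates <- config$baseline_rate + config$gain * (W %*% Z)
  if (config$noise_sd > 0) {
    rates <- rates + stats::rnorm(length(rates)) * config$noise_sd
  }
  region <- make_region_record(rates, config)

  truth <- structure(list(
    ti_basis = ti_basis, td_basis = td_basis,
    ti_curves = ti_curves, td_curves = td_curves,
    amp_ti = amp_ti, amp_td = amp_td,
    ti_variance_fraction = f,
    latents = Z, n_ti = n_ti, n_td = n_td,
    gain = config$gain, baseline = config$baseline_rate,
    events = events, seed = config$seed
  ), class = "synth_truth")

  session <- structure(list(
    regions = list(source = region),
    events = events, behavior = NULL, config = config
  ), class = "session_container")
  list(session = session, truth = truth)
}

# phase in [0, 100): stance [0, 60), swing [60, 100)
cycle_phase <- function(tt, t0, t_off, t1) {
  ph <- ifelse(tt < t_off,
               60 * (tt - t0) / (t_off - t0),
               60 + 40 * (tt - t_off) / (t1 - t_off))
  pmin(pmax(ph, 0), 100 - 1e-9)
}

# linear interpolation on the circular 100-sample grid
interp_circular <- function(curve, phase) {
  lo <- floor(phase)
  w <- phase - lo
  hi <- (lo + 1) %% 100
  curve[lo + 1] * (1 - w) + curve[hi + 1] * w
}

synth_events <- function(config) {
  rows <- list()
  t_cursor <- 0
  for (tk in seq_len(config$n_tasks)) {
    dur <- rtruncnorm1(config$cycles_per_task, config$cycle_duration_mean,
                       config$cycle_duration_sd, 0.3, 1.5)
    sfrac <- rtruncnorm1(config$cycles_per_task, config$stance_fraction_mean,
                         config$stance_fraction_sd, 0.2, 0.8)
    starts <- t_cursor + c(0, cumsum(dur[-length(dur)]))
    rows[[tk]] <- data.frame(
      task_id = tk, cycle_index = seq_len(config$cycles_per_task),
      t_strike_start = starts, t_foot_off = starts + sfrac * dur,
      t_strike_end = starts + dur
    )
    t_cursor <- starts[length(starts)] + dur[length(dur)] + config$task_gap
  }
  ev <- do.call(rbind, rows)
  class(ev) <- c("gait_events", "data.frame")
  ev
}

make_region_record <- function(rates, config) {
  if (config$spike_mode == "poisson") {
    dt <- 1 / config$fs
    lam <- pmax(rates, 0) * dt
    counts <- matrix(stats::rpois(length(lam), lam), nrow(lam))
    spikes <- lapply(seq_len(nrow(counts)), function(ch) {
      idx <- rep(which(counts[ch, ] > 0), counts[ch, counts[ch, ] > 0])
      sort((idx - 0.5) / config$fs)
    })
    list(spike_times = spikes, rates = NULL, fs = config$fs,
         mode = "poisson", n_channels = nrow(rates))
  } else {
    list(spike_times = NULL, rates = rates, fs = config$fs,
         mode = "rates_only", n_channels = nrow(rates))
  }
}

#' Plant a target region driven by a low-rank communication map
#'
#' Target-channel activity is a rank-`comm_rank` linear readout of the
#' source latents, restricted by the alignment parameter alpha
#' (`comm_alignment`): weights `sqrt(alpha)` on TI latents and
#' `sqrt(1 - alpha)` on TD latents. The equivalent source-channel-space map
#' `B_true` (source channels x target channels) is recorded; its column
#' space in source space is the planted communication subspace.
#'
#' @param sim output of [generate_session()] (list with `session`, `truth`).
#' @param n_target_channels target region size (default: same as source).
#' @param name region name (default "target").
#' @return the input list with the target region added to the session and
#'   `truth$comm` populated (`B_true`, its orthonormal source-space basis,
#'   `rank`, `alpha`).
#' @export
plant_comm_target <- function(sim, n_target_channels = NULL,
                              name = "target") {
  session <- sim$session; truth <- sim$truth
  config <- session$config
  q <- n_target_channels %||% config$n_channels
  r <- config$comm_rank
  n_lat <- truth$n_ti + truth$n_td
  if (r > min(n_lat, q)) {
    stop("comm_rank exceeds min(number of source latents, target channels)")
  }
  set.seed(config$seed + 1000003L)
  alpha <- config$comm_alignment
  wts <- c(rep(sqrt(alpha), truth$n_ti), rep(sqrt(1 - alpha), truth$n_td))
  if (r > sum(wts > 0)) {
    stop("comm_rank exceeds the number of latents the map can read at ",
         "alignment ", alpha)
  }
  sel <- which(wts > 0)
  # rank-r factors with equalized variance so every communication dimension
  # carries comparable power (well-conditioned planted map)
  Q <- t(orthonormalize(matrix(stats::rnorm(length(sel) * r), length(sel))))
  f <- Q %*% (wts[sel] * truth$latents[sel, , drop = FALSE])
  f_sd <- sqrt(pmax(rowMeans(f^2) - rowMeans(f)^2, 0))
  f_sd[f_sd == 0] <- 1
  f <- f / f_sd
  P <- orthonormalize(matrix(stats::rnorm(q * r), q)) * sqrt(q / r)
  sig <- P %*% f
  rates <- config$baseline_rate + config$gain * sig
  if (config$noise_sd > 0) {
    rates <- rates + stats::rnorm(length(rates)) * config$noise_sd
  }
  W <- cbind(truth$ti_basis, truth$td_basis)
  B_true <- W[, sel, drop = FALSE] %*% (wts[sel] * t(Q)) %*%
    ((1 / f_sd) * t(P))
  truth$comm <- list(
    B_true = B_true,
    basis = orthonormalize(B_true),
    rank = r, alpha = alpha
  )
  session$regions[[name]] <- make_region_record(rates, config)
  list(session = session, truth = truth)
}

#' Generate EMG envelopes and joint kinematics as linear latent readouts
#'
#' Six EMG envelopes are offset linear readouts of the latents passed
#' through rectification (offsets are large enough that the envelopes stay
#' positive, so the readout is effectively linear with a known weight
#' profile); twelve kinematic channels (x, y, z for four hindlimb
#' landmarks) are linear readouts referenced to the across-landmark mean
#' position at every sample.
#'
#' @param sim output of [generate_session()] (optionally after
#'   [plant_comm_target()]).
#' @return the input list with `session$behavior` set: `emg` (6 x samples,
#'   nonnegative), `kinematics` (12 x samples, landmark-mean-referenced),
#'   `fs`, and readout weights recorded in `truth$behavior`.
#' @export
generate_behavior <- function(sim) {
  session <- sim$session; truth <- sim$truth
  config <- session$config
  set.seed(config$seed + 2000003L)
  Z <- truth$latents
  n_lat <- nrow(Z)
  W_emg <- matrix(stats::rnorm(6 * n_lat), 6, n_lat)
  raw <- W_emg %*% Z
  offs <- 1.2 * apply(abs(raw), 1, max)
  offs[offs == 0] <- 1
  emg <- pmax(raw + offs, 0)

  W_kin <- array(stats::rnorm(3 * 4 * n_lat), c(3, 4, n_lat))
  kin <- array(0, c(3, 4, ncol(Z)))
  for (c3 in 1:3) {
    for (l in 1:4) kin[c3, l, ] <- W_kin[c3, l, , drop = TRUE] %*% Z
    kin[c3, , ] <- sweep(kin[c3, , , drop = TRUE], 2,
                         colMeans(kin[c3, , , drop = TRUE]))
  }
  kin_mat <- matrix(aperm(kin, c(2, 1, 3)), nrow = 12)
  rn <- as.vector(outer(c("hip", "knee", "ankle", "toe"), c("x", "y", "z"),
                        paste, sep = "_"))
  rownames(kin_mat) <- rn
  session$behavior <- list(emg = emg, kinematics = kin_mat, fs = config$fs)
  truth$behavior <- list(W_emg = W_emg, emg_offsets = offs, W_kin = W_kin)
  list(session = session, truth = truth)
}
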