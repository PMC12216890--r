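test_that("the generator is deterministic and validates its configuration", {
  cfg <- small_config()
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$session$regions$source$rates,
                   s2$session$regions$source$rates)
  expect_identical(s1$session$events, s2$session$events)

  expect_error(synth_config(n_channels = 4, n_ti_latents = 4,
                            n_td_latents = 4), "exceed")
  expect_error(synth_config(stance_fraction_mean = 0.1), "stance")
  expect_error(synth_config(ti_variance_fraction = 1.2), "\\[0, 1\\]")
})

test_that("without task-dependent signal every task's trial average coincides", {
  cfg <- small_config(ti_variance_fraction = 1, noise_sd = 0)
  sim <- generate_session(cfg)
  pt <- segment_and_warp(
    zscore_rates(sim$session$regions$source$rates, fs = 1000),
    sim$session$events)
  for (tk in 2:3) {
    expect_equal(pt$trial_avg[, tk, ], pt$trial_avg[, 1, ], tolerance = 0.02)
  }
})

test_that("planted bases are orthonormal and variance fractions exact by construction", {
  cfg <- small_config(ti_variance_fraction = 0.68, cycles_per_task = 50)
  sim <- generate_session(cfg)
  tr <- sim$truth
  W <- cbind(tr$ti_basis, tr$td_basis)
  expect_equal(crossprod(W), diag(ncol(W)), tolerance = 1e-8)

  # direct-projection oracle on the noiseless latent signal: TI share of
  # the planted signal variance equals the configured fraction within 1%
  Z <- tr$latents
  pow <- rowMeans(Z^2)
  ti_frac <- sum(pow[seq_len(tr$n_ti)]) / sum(pow)
  expect_equal(ti_frac, 0.68, tolerance = 0.01)

  # events respect the configured truncation
  dur <- sim$session$events$t_strike_end - sim$session$events$t_strike_start
  expect_true(all(dur > 0.3 & dur < 1.5))
  sf <- (sim$session$events$t_foot_off - sim$session$events$t_strike_start) / dur
  expect_true(all(sf > 0.2 & sf < 0.8))
})

test_that("the planted communication map has the configured rank and alignment", {
  cfg <- small_config(n_channels = 20, comm_rank = 4, comm_alignment = 1,
                      n_ti_latents = 6)
  sim <- plant_comm_target(generate_session(cfg))
  B <- sim$truth$comm$B_true
  sv <- svd(B)$d
  expect_equal(sum(sv > 1e-8 * sv[1]), 4)
  # alpha = 1: the map's source-space column span lies inside the TI basis
  expect_lt(max(principal_angles(sim$truth$comm$basis, sim$truth$ti_basis)),
            1e-4)
  expect_error(plant_comm_target(generate_session(
    small_config(comm_rank = 5, comm_alignment = 0, n_td_latents = 4))),
    "alignment")
})

test_that("poisson spike mode emits spike trains consistent with the rates", {
  cfg <- small_config(n_tasks = 2, cycles_per_task = 8,
                      spike_mode = "poisson", baseline_rate = 40)
  sim <- generate_session(cfg)
  reg <- sim$session$regions$source
  expect_null(reg$rates)
  expect_length(reg$spike_times, cfg$n_channels)
  # mean empirical rate near the baseline (latents average out)
  span <- max(sim$session$events$t_strike_end)
  rate_hat <- mean(vapply(reg$spike_times, length, numeric(1))) / span
  expect_equal(rate_hat, 40, tolerance = 4)
})

test_that("behavioral readouts are rectified-linear EMG and referenced kinematics", {
  cfg <- small_config()
  sim <- generate_behavior(generate_session(cfg))
  beh <- sim$session$behavior
  expect_true(all(beh$emg >= 0))
  # across-landmark mean of the 4 landmark positions is 0 at every sample
  for (coord in 1:3) {
    rows <- (coord - 1) * 4 + 1:4
    expect_lt(max(abs(colMeans(beh$kinematics[rows, ]))), 1e-9)
  }
  # zero latents -> EMG equals the rectified constant offsets
  gap <- which(colSums(abs(sim$truth$latents)) == 0)
  expect_gt(length(gap), 100)
  expect_equal(beh$emg[, gap[5]], unname(sim$truth$behavior$emg_offsets),
               tolerance = 1e-9)
})

test_that("a Wiener readout decodes noiseless planted behavior almost perfectly", {
  cfg <- small_config(noise_sd = 0, n_tasks = 2, cycles_per_task = 20,
                      seed = 13)
  sim <- generate_behavior(generate_session(cfg))
  rates <- sim$session$regions$source$rates
  ev <- sim$session$events
  cal <- which(seq_len(ncol(rates)) / 1000 <
                 max(ev$t_strike_end[ev$task_id == 1]))
  tst <- setdiff(seq_len(ncol(rates)), cal)
  wf <- fit_apply_wiener(rates, sim$session$behavior$emg, fs = 1000,
                         window_ms = 100, calibration_idx = cal,
                         test_idx = list(tst))
  expect_true(all(wf$r2[1, ] >= 0.99))
})
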