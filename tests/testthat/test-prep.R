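test_that("rate estimation matches a brute-force convolution oracle for a single spike", {
  span <- 2
  rm_ <- estimate_rates(list(c(1.0)), span, zscore = FALSE)
  expect_equal(rm_$fs, 1000)
  expect_equal(ncol(rm_$rates), 2000)

  # oracle: impulse -> 10 ms boxcar count (trailing window) -> Hz ->
  # Gaussian (50 ms sd) smoothing, built by direct summation at 2000 Hz
  n_hi <- span * 2000
  base <- numeric(n_hi); base[floor(1.0 * 2000) + 1] <- 1
  box <- numeric(n_hi)
  for (t in seq_len(n_hi)) {
    box[t] <- sum(base[max(1, t - 19):t])
  }
  rate_hz <- box / 0.01
  sdk <- 0.05 * 2000
  x <- seq(-ceiling(4 * sdk), ceiling(4 * sdk))
  k <- exp(-x^2 / (2 * sdk^2)); k <- k / sum(k)
  sm <- numeric(n_hi)
  for (t in seq_len(n_hi)) {
    idx <- t + x
    ok <- idx >= 1 & idx <= n_hi
    sm[t] <- sum(rate_hz[idx[ok]] * k[ok]) / sum(k[ok])
  }
  oracle <- sm[seq(1, n_hi, by = 2)]
  expect_equal(as.numeric(rm_$rates[1, ]), oracle, tolerance = 1e-9)
  expect_equal(which.max(rm_$rates[1, ]), 1001, tolerance = 6)
})

test_that("empty channels yield zero rate and a constant-channel flag", {
  rm_ <- estimate_rates(list(numeric(0), c(0.5, 0.7)), span = 1.5,
                        zscore = FALSE)
  expect_true(all(rm_$rates[1, ] == 0))
  zs <- zscore_rates(rm_)
  expect_true(1 %in% zs$constant_channels)
  expect_false(2 %in% zs$constant_channels)
  expect_equal(mean(zs$rates[2, ]), 0, tolerance = 1e-9)
  expect_equal(sd(zs$rates[2, ]) * sqrt((ncol(zs$rates) - 1) / ncol(zs$rates)),
               1, tolerance = 1e-6)
})

test_that("z-scoring is idempotent", {
  set.seed(1)
  zs <- zscore_rates(matrix(rnorm(300, 5, 3), 3), fs = 100)
  zs2 <- zscore_rates(zs)
  expect_equal(zs2$rates, zs$rates, tolerance = 1e-9)
})

test_that("cycle rejection applies the duration rule then the per-task IQR rule", {
  set.seed(2)
  # 21 cycles: 19 stance 0.50 s, one extreme stance outlier, one long cycle
  stance <- c(rep(0.50, 19), 0.9)
  dur <- rep(1.0, 20)
  starts <- cumsum(c(0, dur[-20]))
  ev <- gait_event_table(1, 1:21,
                         c(starts, 20), c(starts + stance, 20.8),
                         c(starts + dur, 21.6))  # row 21 is 1.6 s long
  rates <- matrix(rnorm(2 * 22 * 1000), 2)
  pt <- segment_and_warp(rates, ev, fs = 1000)
  expect_setequal(pt$rejections$reason, c("duration", "stance_iqr"))
  expect_equal(pt$rejections$cycle_index[pt$rejections$reason == "duration"], 21)
  # IQR oracle computed directly on the duration-surviving stances
  q <- quantile(stance, c(.25, .75), names = FALSE)
  expect_true(stance[20] > q[2] + 1.5 * (q[2] - q[1]))
  expect_equal(pt$rejections$cycle_index[pt$rejections$reason == "stance_iqr"], 20)
  expect_equal(pt$n_cycles[[1]], 19)
})

test_that("rejection is order-independent and scarce tasks raise an error", {
  set.seed(3)
  dur <- runif(12, 0.7, 1.4); dur[3] <- 1.7
  starts <- cumsum(c(0, dur[-12]))
  ev <- gait_event_table(1, 1:12, starts, starts + 0.55 * dur, starts + dur)
  rates <- matrix(rnorm(2 * ceiling(sum(dur) + 1) * 500), 2)
  pt1 <- segment_and_warp(rates, ev, fs = 500)
  perm <- sample(12)
  ev2 <- ev[perm, ]; class(ev2) <- class(ev)
  pt2 <- segment_and_warp(rates, ev2, fs = 500)
  expect_setequal(pt1$rejections$cycle_index, pt2$rejections$cycle_index)
  expect_equal(sort(pt1$events_kept$t_strike_start),
               sort(pt2$events_kept$t_strike_start))

  ev3 <- gait_event_table(1, 1:2, c(0, 1), c(0.6, 1.6), c(1, 2))
  expect_error(segment_and_warp(rates, ev3, fs = 500), "task 1")
})

test_that("warping a linear ramp stays within the input extrema", {
  fs <- 1000
  ev <- gait_event_table(1, 1:3, c(0, 1, 2), c(0.55, 1.62, 2.58), c(1, 2, 3))
  ramp <- matrix(seq(0, 1, length.out = 3.5 * fs), 1)
  pt <- segment_and_warp(ramp, ev, fs = fs)
  for (ci in 1:3) {
    w <- pt$tensor[1, 1, ci, ]
    expect_true(all(diff(w) >= -1e-12))
    expect_lte(max(w), max(ramp)); expect_gte(min(w), min(ramp))
  }
})

test_that("peri-gait statistics recover PGP spread and cross-task correlation", {
  # identical trial-averaged curves in all tasks -> PGP circular sd = 0,
  # and identical cycles -> population cross-task correlation = 1
  curves <- random_curves(4, 5, seed = 9)
  for (tk in 2:5) curves[, tk, ] <- curves[, 1, ]
  st <- perigait_stats(tensor_from_curves(curves, n_cycles = 4))
  expect_equal(st$pgp_sd_mean, 0)
  expect_equal(st$population_cross_task_correlation, 1, tolerance = 1e-12)

  # PGPs uniformly spread at {0,20,40,60,80} -> Rbar = 0, sd = sqrt(2) rad
  curves2 <- array(0, c(1, 5, 100))
  for (tk in 1:5) curves2[1, tk, 20 * (tk - 1) + 1] <- 1
  st2 <- perigait_stats(tensor_from_curves(curves2, n_cycles = 3))
  expect_equal(st2$per_channel$pgp_sd_deg[1], sqrt(2) * 180 / pi,
               tolerance = 1e-6)
  expect_equal(st2$per_channel$pgp_sd_deg[1], 81.03, tolerance = 1e-2)
})
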