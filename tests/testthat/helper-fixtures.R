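# Small, fast study configurations used across the unit tests.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_tasks = 3, cycles_per_task = 15, n_channels = 16,
                   n_ti_latents = 4, n_td_latents = 4, seed = 42)
  do.call(synth_config, utils::modifyList(defaults, args))
}

# perigait tensor built directly from per-task trial curves:
# curves is channels x tasks x 100; each task gets `n_cycles` identical (or
# noise-jittered) cycles.
tensor_from_curves <- function(curves, n_cycles = 5, noise_sd = 0) {
  d <- dim(curves)
  tn <- array(NA_real_, c(d[1], d[2], n_cycles, 100))
  for (ci in seq_len(n_cycles)) {
    tn[, , ci, ] <- curves +
      if (noise_sd > 0) array(rnorm(prod(d), sd = noise_sd), d) else 0
  }
  structure(list(
    tensor = tn,
    trial_avg = colMeans(aperm(tn, c(3, 1, 2, 4)), dims = 1),
    tasks = seq_len(d[2]), n_cycles = rep(n_cycles, d[2]),
    rejections = data.frame(), constant_channels = integer(0)
  ), class = "perigait_tensor")
}

# smooth random per-task curves (channels x tasks x 100)
random_curves <- function(n_ch, n_task, seed = 1) {
  set.seed(seed)
  p <- 0:99
  arr <- array(0, c(n_ch, n_task, 100))
  for (ch in seq_len(n_ch)) {
    for (tk in seq_len(n_task)) {
      arr[ch, tk, ] <- rnorm(1) * sin(2 * pi * p / 100 + runif(1, 0, 2 * pi)) +
        rnorm(1) * cos(4 * pi * p / 100 + runif(1, 0, 2 * pi))
    }
  }
  arr
}

run_prep <- function(sim, region = "source") {
  r <- sim$session$regions[[region]]
  segment_and_warp(zscore_rates(r$rates, fs = r$fs), sim$session$events)
}
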