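#!/usr/bin/env Rscript
# Stage 7: decoding. (a) Gait-event detection with an rLDA decoder
# calibrated on task 1 and tested on tasks 2-5, repeated after removing
# leading task-dependent or task-independent demixed modes (the
# cross-task-generalizing temporal code lives in the TI subspace, so TI
# removal should collapse the F-score while TD removal should not).
# (b) Task classification from the EMG envelopes. (c) Wiener-filter
# reconstruction of EMG envelopes from population rates.

source(file.path("analysis", "common.R"))

sim <- demo_session()
cfg <- demo_config()
zs <- zscore_rates(sim$session$regions$source$rates, fs = cfg$fs)
pt <- segment_and_warp(zs, sim$session$events)
dp <- fit_dpca(pt)

cross_f <- function(rates) {
  dec <- fit_event_decoder(rates, sim$session$events, 1, fs = cfg$fs,
                           L_grid = c(200, 400), B_grid = 5,
                           reg_grid = c(0.01, 0.1))
  run_event_decoder(dec, rates, sim$session$events, tasks = 2:5)$f_score
}

rows <- list(data.frame(removed = "none", k = 0, removed_variance = 0,
                        f_score = cross_f(zs$rates[dp$channels, ])))
for (lab in c("task-independent", "task-dependent")) {
  n_lab <- sum(dp$variance_table$label == lab)
  for (k in unique(c(2, n_lab))) {
    rr <- remove_modes(zs, dp, lab, k)
    rows[[paste(lab, k)]] <- data.frame(
      removed = lab, k = k,
      removed_variance = rr$removed_variance_fraction,
      f_score = cross_f(rr$rates))
  }
}
decoding <- do.call(rbind, rows)
utils::write.csv(decoding, file.path(RESULTS_DIR, "decoding.csv"),
                 row.names = FALSE)
cat("Cross-task gait-event F-scores (calibrated on task 1):\n")
print(decoding, row.names = FALSE)

# task classification from per-cycle warped EMG envelopes
beh_pt <- segment_and_warp(sim$session$behavior$emg, sim$session$events,
                           fs = cfg$fs)
feat <- do.call(rbind, lapply(seq_len(cfg$n_tasks), function(tk) {
  nc <- beh_pt$n_cycles[tk]
  m <- beh_pt$tensor[, tk, seq_len(nc), seq(1, 100, by = 5), drop = FALSE]
  matrix(aperm(m, c(3, 1, 2, 4)), nrow = nc)
}))
labs <- rep(seq_len(cfg$n_tasks), beh_pt$n_cycles)
cls <- classify_task(feat, labs, reg = 0.1)
utils::write.csv(as.data.frame(cls$confusion),
                 file.path(RESULTS_DIR, "task_confusion.csv"),
                 row.names = FALSE)
cat(sprintf("\nTask classification from EMG envelopes: %.1f%% accuracy (chance 20%%).\n",
            100 * cls$accuracy))

# Wiener reconstruction of EMG envelopes (100 ms window), calibrated on
# task 1, evaluated on tasks 2-5
ev <- sim$session$events
t_end1 <- max(ev$t_strike_end[ev$task_id == 1])
all_idx <- seq_len(ncol(zs$rates))
cal <- all_idx[all_idx / cfg$fs < t_end1]
tst <- lapply(2:5, function(tk) {
  t0 <- min(ev$t_strike_start[ev$task_id == tk])
  t1 <- max(ev$t_strike_end[ev$task_id == tk])
  all_idx[all_idx / cfg$fs >= t0 & all_idx / cfg$fs < t1]
})
wf <- fit_apply_wiener(zs$rates, sim$session$behavior$emg, fs = cfg$fs,
                       window_ms = 100, calibration_idx = cal,
                       test_idx = tst)
r2 <- data.frame(task = 2:5, mean_r2 = rowMeans(wf$r2))
utils::write.csv(r2, file.path(RESULTS_DIR, "wiener_emg_r2.csv"),
                 row.names = FALSE)
cat(sprintf("Wiener EMG reconstruction, mean R2 on tasks 2-5: %s.\n",
            paste(round(r2$mean_r2, 3), collapse = ", ")))
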