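#!/usr/bin/env Rscript
# Stage 2: preprocessing and single-channel statistics. Rates are z-scored,
# segmented into gait cycles (duration and stance-IQR rejection rules), and
# warped to the 100-sample phase grid (stance = samples 0-59, swing =
# 60-99). Reports per-channel preferred gait phases, modulation depths, the
# population cross-task correlation, and its bootstrap noise ceiling and
# phase-shuffle chance floor.

source(file.path("analysis", "common.R"))

sim <- demo_session()
pt <- prep_region(sim, "source")

cat(sprintf("Retained %s cycles per task; %d cycles rejected (%s).\n",
            paste(pt$n_cycles, collapse = "/"), nrow(pt$rejections),
            if (nrow(pt$rejections)) paste(unique(pt$rejections$reason),
                                           collapse = ", ") else "none"))

st <- perigait_stats(pt)
utils::write.csv(st$per_channel,
                 file.path(RESULTS_DIR, "perigait_channels.csv"),
                 row.names = FALSE)
utils::write.csv(st$combo_table,
                 file.path(RESULTS_DIR, "cross_task_correlation.csv"),
                 row.names = FALSE)

stat_corr <- function(p) perigait_stats(p)$population_cross_task_correlation
noise <- null_engine(pt, stat_corr, mode = "bootstrap-split", N = 20,
                     seed = 1, observed = st$population_cross_task_correlation,
                     direction = "less")
chance <- null_engine(pt, stat_corr, mode = "phase-shuffle", N = 20,
                      seed = 2, observed = st$population_cross_task_correlation,
                      direction = "greater")

nulls <- rbind(cbind(stat = "cross_task_correlation_noise",
                     stat_result_row(noise)),
               cbind(stat = "cross_task_correlation_chance",
                     stat_result_row(chance)))
utils::write.csv(nulls, file.path(RESULTS_DIR, "correlation_nulls.csv"),
                 row.names = FALSE)

cat(sprintf(
  "Population cross-task correlation %.3f (bootstrap noise ceiling %.3f, phase-shuffle chance %.3f, p = %.4f).\n",
  st$population_cross_task_correlation, noise$null_mean, chance$null_mean,
  chance$p))
cat(sprintf("Mean PGP circular s.d. across tasks: %.1f deg (chance for 5 uniform angles: 60.3 deg).\n",
            st$pgp_sd_mean))
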