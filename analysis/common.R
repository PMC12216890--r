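# Shared study configuration for the analysis scripts. Every script
# regenerates the session deterministically from this config (cheap), so no
# bulky rate matrices need to be stored between stages.

library(gaitmodes)

RESULTS_DIR <- file.path("results", "analysis")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

demo_config <- function() {
  synth_config(
    n_tasks = 5, cycles_per_task = 60, n_channels = 32,
    ti_variance_fraction = 0.68,   # S1-like regime: TI-dominated
    comm_rank = 3, comm_alignment = 1,
    seed = 20260925
  )
}

demo_session <- function() {
  generate_behavior(plant_comm_target(generate_session(demo_config())))
}

prep_region <- function(sim, region) {
  r <- sim$session$regions[[region]]
  segment_and_warp(zscore_rates(r$rates, fs = r$fs), sim$session$events)
}
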