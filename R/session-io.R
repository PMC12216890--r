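#' Write a session container to a plain-text directory layout
#'
#' Layout: `meta.json` (sampling rates, config, config hash),
#' `events.csv` (task_id, cycle_index, t_strike_start, t_foot_off,
#' t_strike_end; seconds, 6 decimals), `regions/<name>_rates.csv` or
#' `regions/<name>_spikes.csv`, and optional `behavior/emg.csv`,
#' `behavior/kinematics.csv`.
#'
#' @param session `session_container`.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_container"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "regions"), showWarnings = FALSE)
  ev <- session$events
  evo <- data.frame(
    task_id = ev$task_id, cycle_index = ev$cycle_index,
    t_strike_start = sprintf("%.6f", ev$t_strike_start),
    t_foot_off = sprintf("%.6f", ev$t_foot_off),
    t_strike_end = sprintf("%.6f", ev$t_strike_end)
  )
  utils::write.csv(evo, file.path(path, "events.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- list(
    regions = lapply(session$regions, function(r) {
      list(fs = r$fs, mode = r$mode, n_channels = r$n_channels)
    }),
    config = unclass(session$config),
    config_hash = config_hash(session$config),
    behavior_fs = if (!is.null(session$behavior)) session$behavior$fs else NULL
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  for (nm in names(session$regions)) {
    r <- session$regions[[nm]]
    if (!is.null(r$rates)) {
      utils::write.csv(r$rates,
                       file.path(path, "regions", paste0(nm, "_rates.csv")),
                       row.names = FALSE)
    }
    if (!is.null(r$spike_times)) {
      sp <- do.call(rbind, lapply(seq_along(r$spike_times), function(ch) {
        if (length(r$spike_times[[ch]]) == 0) return(NULL)
        data.frame(channel = ch, time = sprintf("%.6f", r$spike_times[[ch]]))
      }))
      utils::write.csv(sp,
                       file.path(path, "regions", paste0(nm, "_spikes.csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  if (!is.null(session$behavior)) {
    dir.create(file.path(path, "behavior"), showWarnings = FALSE)
    utils::write.csv(session$behavior$emg,
                     file.path(path, "behavior", "emg.csv"), row.names = FALSE)
    utils::write.csv(session$behavior$kinematics,
                     file.path(path, "behavior", "kinematics.csv"),
                     row.names = TRUE)
  }
  invisible(path)
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)[order(names(unclass(config)))]),
             collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %% 2^31)
}

#' Read a session container written by [write_session()]
#'
#' Validates event ordering (naming the offending row), requires
#' sampling-rate attributes, and checks the stored config hash.
#'
#' @param path directory.
#' @return `session_container`.
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("missing meta.json in ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  ev_raw <- utils::read.csv(file.path(path, "events.csv"))
  events <- gait_event_table(ev_raw$task_id, ev_raw$cycle_index,
                             ev_raw$t_strike_start, ev_raw$t_foot_off,
                             ev_raw$t_strike_end)
  regions <- list()
  for (nm in names(meta$regions)) {
    rmeta <- meta$regions[[nm]]
    if (is.null(rmeta$fs)) stop("region ", nm, " lacks a sampling-rate attribute")
    rec <- list(fs = rmeta$fs, mode = rmeta$mode, n_channels = rmeta$n_channels,
                rates = NULL, spike_times = NULL)
    rf <- file.path(path, "regions", paste0(nm, "_rates.csv"))
    sf <- file.path(path, "regions", paste0(nm, "_spikes.csv"))
    if (file.exists(rf)) {
      rec$rates <- as.matrix(utils::read.csv(rf))
      dimnames(rec$rates) <- NULL
    }
    if (file.exists(sf)) {
      sp <- utils::read.csv(sf)
      rec$spike_times <- lapply(seq_len(rmeta$n_channels), function(ch) {
        sp$time[sp$channel == ch]
      })
    }
    if (is.null(rec$rates) && is.null(rec$spike_times)) {
      stop("region ", nm, " has neither rates nor spike times")
    }
    regions[[nm]] <- rec
  }
  span <- max(events$t_strike_end)
  for (nm in names(regions)) {
    r <- regions[[nm]]
    n_samp <- if (!is.null(r$rates)) ncol(r$rates) else Inf
    if (span * r$fs > n_samp + 1) {
      stop("event times exceed the recording span of region ", nm)
    }
  }
  cfg <- meta$config
  if (!is.null(cfg)) class(cfg) <- "synth_config"
  behavior <- NULL
  if (dir.exists(file.path(path, "behavior"))) {
    emg <- as.matrix(utils::read.csv(file.path(path, "behavior", "emg.csv")))
    dimnames(emg) <- NULL
    kin <- utils::read.csv(file.path(path, "behavior", "kinematics.csv"),
                           row.names = 1)
    behavior <- list(emg = emg, kinematics = as.matrix(kin),
                     fs = meta$behavior_fs)
  }
  structure(list(regions = regions, events = events, behavior = behavior,
                 config = cfg), class = "session_container")
}

#' Run the full synthetic-session analysis pipeline
#'
#' simulate -> prep -> manifold -> dPCA -> communication -> principal
#' angles -> decoding, writing one tidy CSV (or JSON) per stage plus a log
#' with the seed and stage timings. Any stage failure aborts with the stage
#' name.
#'
#' @param config `synth_config`.
#' @param out_dir results directory.
#' @param battery_reps channel-subsample repetitions for the dimensionality
#'   battery (default 50 for a fast demonstration run).
#' @param comm_tasks task indices for the communication fits (default 1).
#' @param decode_removal mode-removal depths for the decoding stage
#'   (default `c(0, 3)`).
#' @return list of per-stage results, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, battery_reps = 50,
                         comm_tasks = 1, decode_removal = c(0, 3)) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_tasks < 1) stop("config with no tasks")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = config$seed, r_version = R.version.string, stages = list())
  res <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log$stages[[name]] <<- round(proc.time()[3] - t0, 2)
    out
  }

  res$sim <- stage("simulate", {
    sim <- generate_session(config)
    sim <- plant_comm_target(sim)
    generate_behavior(sim)
  })
  res$prep <- stage("prep", {
    pts <- lapply(res$sim$session$regions, function(r) {
      segment_and_warp(zscore_rates(r$rates, fs = r$fs),
                       res$sim$session$events)
    })
    st <- perigait_stats(pts$source)
    utils::write.csv(st$per_channel,
                     file.path(out_dir, "perigait_channels.csv"),
                     row.names = FALSE)
    utils::write.csv(pts$source$rejections,
                     file.path(out_dir, "rejections.csv"), row.names = FALSE)
    list(tensors = pts, stats = st)
  })
  pts <- res$prep$tensors
  res$manifold <- stage("manifold", {
    bat <- dimensionality_battery(pts$source,
                                  n_sub = min(32, config$n_channels),
                                  reps = battery_reps, seed = config$seed)
    ai <- alignment_index_session(pts$source)
    df <- data.frame(
      statistic = c(paste0("single_task_d_", seq_along(bat$single_task_d)),
                    "all_task_d", "delta_dim",
                    paste0("leave_one_out_", seq_along(bat$leave_one_out)),
                    "mean_alignment_index"),
      value = c(bat$single_task_d, bat$all_task_d, bat$delta_dim,
                bat$leave_one_out, ai$mean_ai)
    )
    utils::write.csv(df, file.path(out_dir, "manifold.csv"), row.names = FALSE)
    list(battery = bat, ai = ai)
  })
  res$dpca <- stage("dpca", {
    dp <- fit_dpca(pts$source)
    vt <- variance_table(dp)
    utils::write.csv(vt$per_mode, file.path(out_dir, "dpca_modes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(subspace = as.list(vt$subspace),
           subspace_share = as.list(vt$subspace_share),
           pie = as.list(vt$pie), residual_pct = vt$residual_pct),
      file.path(out_dir, "dpca_summary.json"), auto_unbox = TRUE, digits = NA)
    dp
  })
  res$comms <- stage("comms", {
    fits <- lapply(comm_tasks, function(tk) {
      fit_communication(pts$source, pts$target, tk)
    })
    df <- data.frame(
      task = comm_tasks,
      m_rrr = vapply(fits, `[[`, numeric(1), "m_rrr"),
      r2_ridge = vapply(fits, `[[`, numeric(1), "r2_ridge"),
      lambda_star = vapply(fits, function(f) f$ridge$lambda_star, numeric(1))
    )
    utils::write.csv(df, file.path(out_dir, "communication.csv"),
                     row.names = FALSE)
    fits
  })
  res$geom <- stage("geomstats", {
    ti5 <- dpca_subspace(res$dpca, "task-independent", 5, strict = FALSE)
    td5 <- dpca_subspace(res$dpca, "task-dependent", 5, strict = FALSE)
    rows <- lapply(seq_along(comm_tasks), function(i) {
      comm <- communication_basis(res$comms[[i]])
      data.frame(task = comm_tasks[i],
                 delta_angles = mean(principal_angles(comm, td5)) -
                   mean(principal_angles(comm, ti5)))
    })
    df <- do.call(rbind, rows)
    chance <- null_engine(NULL, mode = "pgp-uniform", N = 2000,
                          seed = config$seed)
    utils::write.csv(df, file.path(out_dir, "delta_angles.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(pgp_chance_mean = chance$null_mean, pgp_chance_sd = chance$null_sd),
      file.path(out_dir, "chance_levels.json"), auto_unbox = TRUE, digits = NA)
    list(delta = df, pgp_chance = chance)
  })
  res$decode <- stage("decode", {
    zs <- zscore_rates(res$sim$session$regions$source$rates, fs = config$fs)
    test_tasks <- setdiff(seq_len(config$n_tasks), 1)
    rows <- list()
    for (k in decode_removal) {
      for (lab in if (k == 0) "none" else c("task-independent",
                                            "task-dependent")) {
        rr <- if (k == 0) {
          list(rates = zs$rates[res$dpca$channels, , drop = FALSE],
               removed_variance_fraction = 0)
        } else {
          remove_modes(zs, res$dpca, lab, k)
        }
        dec <- fit_event_decoder(rr$rates, res$sim$session$events, 1,
                                 fs = config$fs,
                                 L_grid = c(200, 400), B_grid = 5,
                                 reg_grid = c(0.01, 0.1))
        sc <- run_event_decoder(dec, rr$rates, res$sim$session$events,
                                tasks = test_tasks)
        rows[[paste(k, lab)]] <- data.frame(
          removed = lab, k = k,
          removed_variance = rr$removed_variance_fraction,
          f_score = sc$f_score)
      }
    }
    df <- do.call(rbind, rows)
    utils::write.csv(df, file.path(out_dir, "decoding.csv"),
                     row.names = FALSE)
    df
  })
  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
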