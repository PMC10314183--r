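# Pipeline driver ------------------------------------------------------------
#
# The analysis stages have a fixed order — baseline, events, summarize,
# circadian — because each consumes the previous stage's output. The
# pipeline driver enforces that order, reads everything it needs from a
# structured YAML configuration, and writes the full CSV output set plus a
# provenance copy of the resolved configuration and a run log.

config_defaults <- function() {
  list(
    input = list(paths = character(0), tz = "UTC", dialect = list()),
    trim = NULL,
    conditions = NULL,
    exclude = NULL,
    lights = list(on = "09:00:00", off = "21:00:00"),
    baseline = list(method = "rm", rm_window_minutes = 5, chunk_hours = 24,
                    als = list(lambda = NULL, p = 0.01, max_iter = 20, tol = 0)),
    events = list(feeding_minimum = 5, feeding_threshold = 15,
                  consecutive_licks = 2, gap = "5 samples",
                  threshold_mode = "peak"),
    bins = list(interval_minutes = 60, func = "sum", error_bar = "SEM"),
    normalize = list(enabled = FALSE, mode = "sum"),
    circadian = list(dd_start = NULL, dd_end = NULL, period_min_h = 16,
                     period_max_h = 32, alpha = 0.05,
                     bin_interval_minutes = 30),
    output = list(dir = "flicrhythm-out"),
    simulate = NULL,
    seed = NULL
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    if (!key %in% names(defaults) && length(path) < 2 &&
        !is.null(names(defaults))) {
      abort(paste0("Unknown configuration key: ",
                   paste(c(path, key), collapse = ".")))
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read and validate an experiment configuration
#'
#' Loads a YAML configuration, fills defaults, rejects unknown keys and
#' checks cross-field constraints (the DD window must lie within the trim
#' window; condition entries must reference monitors present among the
#' inputs).
#'
#' @param path Path to a YAML file.
#' @param overrides Optional named list of dotted keys to override, e.g.
#'   `list("events.feeding_minimum" = 10)`.
#' @return A validated configuration list of class `flic_config`.
#' @export
read_experiment_config <- function(path, overrides = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(config_defaults(), user)
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    ref <- cfg
    for (p in head(parts, -1)) {
      if (!p %in% names(ref)) abort(paste0("Unknown configuration key: ", key))
      ref <- ref[[p]]
    }
    cfg[[parts]] <- override_coerce(cfg[[parts]], overrides[[key]])
  }
  validate_config(cfg)
}

override_coerce <- function(old, value) {
  if (is.numeric(old) && !is.na(suppressWarnings(as.numeric(value)))) {
    return(as.numeric(value))
  }
  if (is.logical(old)) return(as.logical(value))
  value
}

validate_config <- function(cfg) {
  if (!is.null(cfg$trim) && !is.null(cfg$circadian$dd_start)) {
    if (as.Date(cfg$circadian$dd_start) < as.Date(cfg$trim$start) ||
        as.Date(cfg$circadian$dd_end %||% cfg$trim$end) > as.Date(cfg$trim$end)) {
      abort("Configuration error at circadian.dd_start/dd_end: the DD window must lie within the trim window.")
    }
  }
  if (cfg$circadian$period_min_h >= cfg$circadian$period_max_h) {
    abort("Configuration error at circadian.period_min_h: must be below period_max_h.")
  }
  if (!cfg$baseline$method %in% c("rm", "als")) {
    abort("Configuration error at baseline.method: must be 'rm' or 'als'.")
  }
  structure(cfg, class = "flic_config")
}

config_dialect <- function(cfg) {
  do.call(flic_dialect, cfg$input$dialect %||% list())
}

# Combine per-monitor event tables into one, merging the well universes and
# recording spans carried as attributes.
combine_events <- function(event_tables) {
  if (length(event_tables) == 1) return(event_tables[[1]])
  out <- dplyr::bind_rows(lapply(event_tables, as_tibble))
  structure(
    out,
    wells = dplyr::bind_rows(lapply(event_tables, attr, "wells")),
    span_start = min(do.call(c, lapply(event_tables, attr, "span_start"))),
    span_end = max(do.call(c, lapply(event_tables, attr, "span_end"))),
    sample_interval_ms = attr(event_tables[[1]], "sample_interval_ms"),
    class = c("flic_events", class(tibble()))
  )
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in their required order and writes the
#' output CSV set (events, individual and group statistics, binned series,
#' day/night table, events per day, periodogram tables), a provenance copy
#' of the resolved configuration, and a run log. Given identical inputs
#' and configuration the outputs are byte-identical.
#'
#' @param config A `flic_config` (see [read_experiment_config()]) or a path
#'   to a YAML file.
#' @param stages Subset of `c("baseline", "events", "summarize",
#'   "circadian")`. Later stages need their prerequisites in the same run:
#'   events needs baseline; summarize and circadian need events.
#' @param outdir Output directory; overrides `output.dir` from the
#'   configuration.
#' @return Invisibly, a named list of the result objects.
#' @export
run_pipeline <- function(config,
                         stages = c("baseline", "events", "summarize",
                                    "circadian"),
                         outdir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "flic_config"))
  all_stages <- c("baseline", "events", "summarize", "circadian")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  prereq <- list(events = "baseline", summarize = "events",
                 circadian = "events")
  for (s in stages) {
    need <- prereq[[s]]
    if (!is.null(need) && !need %in% stages) {
      abort(paste0("Stage '", s, "' requires stage '", need,
                   "' to run first; add it to `stages`."))
    }
  }

  outdir <- outdir %||% config$output$dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log_line <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    inform(msg)
  }
  logged <- function(expr) {
    withCallingHandlers(
      expr,
      warning = function(w) {
        writeLines(paste0("WARNING: ", conditionMessage(w)), log_con)
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        writeLines(sub("\n$", "", conditionMessage(m)), log_con)
        invokeRestart("muffleMessage")
      }
    )
  }

  results <- list()
  dialect <- config_dialect(config)
  tz <- config$input$tz %||% "UTC"
  paths <- config$input$paths
  if (length(paths) == 0) abort("Configuration error at input.paths: no input files.")

  log_line("Reading ", length(paths), " input file(s)")
  monitors_of <- vapply(paths, monitor_from_filename, integer(1),
                        pattern = dialect$monitor_pattern)
  raw <- lapply(split(paths, monitors_of), function(p) {
    logged(read_flic_monitor(p, dialect = dialect, tz = tz))
  })

  if (!is.null(config$trim)) {
    log_line("Trimming to ", config$trim$start, " .. ", config$trim$end)
    raw <- lapply(raw, function(t) {
      logged(trim_by_date(t, config$trim$start, config$trim$end))
    })
  }

  monitor_ids <- as.integer(names(raw))
  cond_monitors <- unlist(lapply(config$conditions, `[[`, "monitor"))
  if (!is.null(cond_monitors) &&
      !all(as.integer(cond_monitors) %in% monitor_ids)) {
    abort("Configuration error at conditions: referenced monitor(s) absent from inputs.")
  }
  conditions <- assign_conditions(
    config$conditions, monitors = monitor_ids,
    n_wells = length(dialect$well_columns), exclude = config$exclude
  )
  results$conditions <- conditions

  if ("baseline" %in% stages) {
    log_line("Baselining (", config$baseline$method, ")")
    baselined <- lapply(raw, function(t) {
      logged(baseline_table(
        t, method = config$baseline$method,
        rm_window_minutes = config$baseline$rm_window_minutes,
        als_lambda = config$baseline$als$lambda,
        als_p = config$baseline$als$p,
        als_max_iter = config$baseline$als$max_iter,
        als_tol = config$baseline$als$tol,
        chunk_hours = config$baseline$chunk_hours
      ))
    })
    results$baselined <- baselined
  }

  if ("events" %in% stages) {
    params <- event_params(
      feeding_minimum = config$events$feeding_minimum,
      feeding_threshold = config$events$feeding_threshold,
      consecutive_licks = config$events$consecutive_licks,
      gap = config$events$gap,
      threshold_mode = config$events$threshold_mode
    )
    log_line("Calling events")
    per_monitor <- lapply(names(results$baselined), function(id) {
      sub_cond <- conditions[conditions$monitor == as.integer(id), ,
                             drop = FALSE]
      logged(call_all_events(results$baselined[[id]], params,
                             conditions = sub_cond, quiet = FALSE))
    })
    events <- combine_events(per_monitor)
    results$events <- events
    write_table_csv(as_tibble(events), file.path(outdir, "events.csv"))
  }

  if ("summarize" %in% stages) {
    log_line("Summarising")
    events <- results$events
    schedule <- light_schedule(config$lights$on, config$lights$off)
    totals <- individual_totals(events)
    results$individual_stats <- totals
    write_table_csv(totals, file.path(outdir, "individual_stats.csv"))
    gstats <- group_stats(totals)
    results$group_stats <- gstats
    write_table_csv(gstats, file.path(outdir, "group_stats.csv"))
    results$outliers <- flag_outliers(totals)
    write_table_csv(results$outliers, file.path(outdir, "outliers.csv"))
    epd <- events_per_day(events)
    results$events_per_day <- epd
    write_table_csv(epd, file.path(outdir, "events_per_day.csv"))
    dn <- split_day_night(events, schedule)
    results$day_night <- dn
    write_table_csv(dn, file.path(outdir, "day_night.csv"))

    binned <- logged(bin_events(events,
                                interval_minutes = config$bins$interval_minutes,
                                func = config$bins$func))
    if (isTRUE(config$normalize$enabled)) {
      binned <- logged(normalize_wells(binned, mode = config$normalize$mode))
    }
    results$binned <- binned
    write_table_csv(as_tibble(binned), file.path(outdir, "binned.csv"))
    profile <- tryCatch(
      daily_profile(binned, error_bar = config$bins$error_bar),
      error = function(e) {
        log_line("Daily profile skipped: ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(profile)) {
      results$daily_profile <- profile
      write_table_csv(profile, file.path(outdir, "daily_profile.csv"))
    }
  }

  if ("circadian" %in% stages) {
    log_line("Circadian analysis")
    events <- results$events
    binned_c <- logged(bin_events(
      events, interval_minutes = config$circadian$bin_interval_minutes
    ))
    if (isTRUE(config$normalize$enabled)) {
      binned_c <- logged(normalize_wells(binned_c,
                                         mode = config$normalize$mode))
    }
    pg <- logged(periodogram(
      binned_c,
      dd_start = config$circadian$dd_start,
      dd_end = config$circadian$dd_end,
      period_range_h = c(config$circadian$period_min_h,
                         config$circadian$period_max_h),
      alpha = config$circadian$alpha
    ))
    results$periodogram <- pg
    summ <- periodogram_summary(pg)
    results$periodogram_summary <- summ
    write_table_csv(summ$table, file.path(outdir, "periodogram.csv"))
    write_table_csv(summ$mean_curve,
                    file.path(outdir, "periodogram_mean_curve.csv"))
  }

  yaml::write_yaml(unclass(config), file.path(outdir, "config_used.yaml"))
  log_line("Done; outputs in ", outdir)
  invisible(results)
}

# Rate-profile construction from configuration lists --------------------------

parse_profile_spec <- function(spec) {
  if (inherits(spec, "flic_rate_profile")) return(spec)
  kind <- spec$kind %||% abort("Profile entry needs a `kind`.")
  switch(
    kind,
    flat = rate_flat(spec$rate %||% 3),
    sinusoidal = rate_sinusoidal(spec$mesor, spec$amplitude,
                                 spec$period_h %||% 24, spec$phase_h %||% 0),
    bimodal = rate_bimodal(spec$r_base, spec$peak_height,
                           spec$peak_width_h %||% 1,
                           spec$lights_on %||% "09:00:00",
                           spec$lights_off %||% "21:00:00"),
    step = rate_step(spec$day_rate, spec$night_rate,
                     spec$lights_on %||% "09:00:00",
                     spec$lights_off %||% "21:00:00"),
    abort(paste0("Unknown profile kind: ", kind))
  )
}

#' Simulate an experiment from a configuration and write its files
#'
#' Reads the `simulate` section of the configuration, generates the
#' synthetic recording and writes a FLIC-dialect CSV per monitor, the
#' ground-truth bout table, and the resolved configuration (provenance).
#'
#' @param config A `flic_config` or path to one.
#' @param outdir Output directory for the simulated CSVs; overrides
#'   `output.dir`.
#' @return Invisibly, the `flic_simulation` object.
#' @export
simulate_from_config <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  sim_cfg <- config$simulate
  if (is.null(sim_cfg)) abort("Configuration has no `simulate` section.")
  outdir <- outdir %||% config$output$dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  profiles <- sim_cfg$profiles
  n_wells <- sim_cfg$n_wells %||% 12
  profile_arg <- if (is.null(profiles)) {
    rate_flat(3)
  } else if (!is.null(profiles$kind)) {
    parse_profile_spec(profiles)
  } else {
    # per-well entries: list(wells =, profile =, dd_profile = optional)
    per_well <- vector("list", n_wells)
    for (entry in profiles) {
      p <- parse_profile_spec(entry$profile)
      pd <- if (!is.null(entry$dd_profile)) parse_profile_spec(entry$dd_profile) else p
      for (w in unlist(entry$wells)) per_well[[w]] <- list(ld = p, dd = pd)
    }
    if (any(vapply(per_well, is.null, logical(1)))) {
      abort("simulate.profiles does not cover every well.")
    }
    per_well
  }

  params <- simulation_params(
    n_wells = n_wells,
    n_ld_days = sim_cfg$n_ld_days %||% 3,
    n_dd_days = sim_cfg$n_dd_days %||% 4,
    duration_days = sim_cfg$duration_days %||%
      ((sim_cfg$n_ld_days %||% 3) + (sim_cfg$n_dd_days %||% 4)),
    sample_interval_ms = sim_cfg$sample_interval_ms %||% 200,
    lights_on = config$lights$on, lights_off = config$lights$off,
    start = sim_cfg$start %||% "2021-07-01 00:00:00",
    tz = config$input$tz %||% "UTC",
    baseline_level = sim_cfg$baseline_level %||% 100,
    drift_amplitude = sim_cfg$drift_amplitude %||% 20,
    noise_sd = sim_cfg$noise_sd %||% 2,
    bout_rate_profile = profile_arg,
    bout_duration_s = sim_cfg$bout_duration_s %||% 5,
    bout_amplitude = sim_cfg$bout_amplitude %||% 40,
    monitor_id = sim_cfg$monitor_id %||% 1,
    seed = config$seed
  )
  sim <- simulate_experiment(params)
  csv_path <- file.path(outdir, paste0("DFM_", params$monitor_id, ".csv"))
  write_flic_csv(sim$signals, csv_path)
  write_table_csv(sim$truth, file.path(outdir, "truth.csv"))
  yaml::write_yaml(unclass(config), file.path(outdir, "config_used.yaml"))
  inform(paste0("Simulated recording written to ", csv_path))
  invisible(sim)
}
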