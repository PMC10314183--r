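#' Bout-rate profiles
#'
#' Feeding bouts are drawn from an inhomogeneous Poisson process whose rate
#' (events/hour) varies with time of day. Four profile families are
#' provided:
#'
#' * `rate_flat(rate)` — constant rate; the arrhythmic ("clock-mutant")
#'   phenotype.
#' * `rate_sinusoidal(mesor, amplitude, period_h, phase_h)` — cosine rate
#'   `mesor + amplitude * cos(2*pi*(t - phase_h)/period_h)` peaking at
#'   `phase_h`. With `period_h != 24` the rhythm free-runs, so the profile
#'   is evaluated on absolute time rather than wrapped time of day.
#' * `rate_bimodal(r_base, peak_height, peak_width_h, lights_on, lights_off)`
#'   — a constant base rate plus Gaussian peaks of height `peak_height`
#'   (events/hour above base) and standard deviation `peak_width_h`, centred
#'   exactly at lights-on and lights-off; the classic anticipatory
#'   morning/evening feeding phenotype.
#' * `rate_step(day_rate, night_rate, lights_on, lights_off)` — distinct
#'   constant day and night rates (light-driven "masking").
#'
#' All rates must be nonnegative; the bimodal and sinusoidal profiles are
#' checked to stay nonnegative over the whole day.
#'
#' @param rate,mesor,amplitude,r_base,peak_height,day_rate,night_rate
#'   Rates in events/hour.
#' @param period_h,phase_h,peak_width_h Times in hours.
#' @param lights_on,lights_off Times of day (see [light_schedule()]).
#' @return An object of class `flic_rate_profile`.
#' @name rate_profiles
NULL

new_rate_profile <- function(kind, params, fn) {
  structure(list(kind = kind, params = params, fn = fn),
            class = "flic_rate_profile")
}

#' @rdname rate_profiles
#' @export
rate_flat <- function(rate) {
  if (rate < 0) abort("`rate` must be >= 0.")
  new_rate_profile("flat", list(rate = rate),
                   function(t_h) rep(rate, length(t_h)))
}

#' @rdname rate_profiles
#' @export
rate_sinusoidal <- function(mesor, amplitude, period_h = 24, phase_h = 0) {
  if (mesor < 0 || amplitude < 0 || period_h <= 0) {
    abort("`mesor` and `amplitude` must be >= 0 and `period_h` > 0.")
  }
  if (amplitude > mesor) {
    abort("`amplitude` must not exceed `mesor` (rates must stay >= 0).")
  }
  new_rate_profile(
    "sinusoidal",
    list(mesor = mesor, amplitude = amplitude, period_h = period_h,
         phase_h = phase_h),
    function(t_h) mesor + amplitude * cos(2 * pi * (t_h - phase_h) / period_h)
  )
}

#' @rdname rate_profiles
#' @export
rate_bimodal <- function(r_base, peak_height, peak_width_h = 1,
                         lights_on = "09:00:00", lights_off = "21:00:00") {
  if (r_base < 0 || peak_height < 0 || peak_width_h <= 0) {
    abort("Rates must be >= 0 and `peak_width_h` > 0.")
  }
  on_h <- parse_time_of_day(lights_on) / 3600
  off_h <- parse_time_of_day(lights_off) / 3600
  # Gaussian bump wrapped on the 24 h circle
  bump <- function(t, centre) {
    exp(-0.5 * ((t - centre - 24) / peak_width_h)^2) +
      exp(-0.5 * ((t - centre) / peak_width_h)^2) +
      exp(-0.5 * ((t - centre + 24) / peak_width_h)^2)
  }
  new_rate_profile(
    "bimodal",
    list(r_base = r_base, peak_height = peak_height,
         peak_width_h = peak_width_h, lights_on_h = on_h, lights_off_h = off_h),
    function(t_h) {
      t <- t_h %% 24
      r_base + peak_height * (bump(t, on_h) + bump(t, off_h))
    }
  )
}

#' @rdname rate_profiles
#' @export
rate_step <- function(day_rate, night_rate,
                      lights_on = "09:00:00", lights_off = "21:00:00") {
  if (day_rate < 0 || night_rate < 0) abort("Rates must be >= 0.")
  schedule <- light_schedule(lights_on, lights_off)
  new_rate_profile(
    "step",
    list(day_rate = day_rate, night_rate = night_rate,
         lights_on = lights_on, lights_off = lights_off),
    function(t_h) {
      ifelse(is_daytime((t_h %% 24) * 3600, schedule), day_rate, night_rate)
    }
  )
}

#' Evaluate a bout-rate profile at a time of day
#'
#' @param profile A `flic_rate_profile`.
#' @param t_h Time(s) in hours; time of day in `[0, 24)` for the daily
#'   profiles, absolute hours for a free-running sinusoid.
#' @return Rate(s) in events/hour, always nonnegative.
#' @export
#' @examples
#' rate_profile(rate_flat(2), c(0, 12, 23.5))
rate_profile <- function(profile, t_h) {
  stopifnot(inherits(profile, "flic_rate_profile"))
  if (any(t_h < 0)) abort("`t_h` must be >= 0.")
  r <- profile$fn(t_h)
  pmax(r, 0)
}

#' @export
print.flic_rate_profile <- function(x, ...) {
  cat("<flic_rate_profile> ", x$kind, ": ",
      paste(names(x$params), unlist(lapply(x$params, format)),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulation parameters
#'
#' Describes a synthetic FLIC experiment: the board layout, the recording
#' span (light-dark days followed by constant-darkness days), the sensor
#' model (baseline level, slow drift, Gaussian read noise) and the feeding
#' model (per-well bout-rate profiles, mean bout duration, bout amplitude).
#'
#' The defaults emulate a standard one-week assay: 12 wells sampled at 5 Hz
#' for 3 LD + 4 DD days starting 2021-07-01 with lights at 09:00/21:00, a
#' sensor baseline of 100 a.u. drifting by ~20 a.u./day, read noise of
#' 2 a.u., and rectangular feeding bouts of 40 a.u. lasting 5 s on average
#' at 3 bouts/hour.
#'
#' @param n_wells Number of wells.
#' @param n_ld_days,n_dd_days Days under light-dark cycles and under
#'   constant darkness. `duration_days` defaults to their sum.
#' @param duration_days Total recording length in days.
#' @param sample_interval_ms Milliseconds between samples.
#' @param lights_on,lights_off Light schedule (see [light_schedule()]).
#' @param start Wall-clock start of the recording.
#' @param tz Time zone.
#' @param baseline_level Mean sensor reading with no fly contact (a.u.).
#' @param drift_amplitude Scale of the slow baseline drift, a.u. per day
#'   (standard deviation of the daily random-walk increment). The drift is
#'   a Gaussian random walk on hourly knots, spline-interpolated to sample
#'   resolution, so its timescale is well above one hour.
#' @param noise_sd Gaussian read-noise standard deviation (a.u.).
#' @param bout_rate_profile One `flic_rate_profile` shared by all wells, or
#'   a list of length `n_wells`. Each per-well entry may itself be a list
#'   `list(ld = profile, dd = profile)` to model light-driven behaviour that
#'   disappears in constant darkness.
#' @param bout_duration_s Mean bout duration in seconds (exponentially
#'   distributed, floored at one sample).
#' @param bout_amplitude Signal deflection during a bout (a.u.). A warning
#'   is issued when it does not exceed `noise_sd`.
#' @param monitor_id Monitor number stamped on the output.
#' @param seed Optional RNG seed; the same seed reproduces the experiment
#'   exactly.
#' @return A `flic_sim_params` object.
#' @export
simulation_params <- function(n_wells = 12,
                              n_ld_days = 3,
                              n_dd_days = 4,
                              duration_days = n_ld_days + n_dd_days,
                              sample_interval_ms = 200,
                              lights_on = "09:00:00",
                              lights_off = "21:00:00",
                              start = "2021-07-01 00:00:00",
                              tz = "UTC",
                              baseline_level = 100,
                              drift_amplitude = 20,
                              noise_sd = 2,
                              bout_rate_profile = rate_flat(3),
                              bout_duration_s = 5,
                              bout_amplitude = 40,
                              monitor_id = 1,
                              seed = NULL) {
  if (duration_days <= 0) abort("Zero-length experiment: `duration_days` must be > 0.")
  if (sample_interval_ms <= 0) abort("`sample_interval_ms` must be > 0.")
  if (noise_sd < 0 || drift_amplitude < 0) abort("Noise and drift scales must be >= 0.")
  if (bout_duration_s <= 0) abort("`bout_duration_s` must be > 0.")
  if (bout_amplitude <= noise_sd) {
    warn("`bout_amplitude` does not exceed `noise_sd`; events will be hard to detect.")
  }
  profiles <- normalize_profiles(bout_rate_profile, n_wells)
  start <- as.POSIXct(start, tz = tz)
  structure(
    list(
      n_wells = as.integer(n_wells), n_ld_days = n_ld_days,
      n_dd_days = n_dd_days, duration_days = duration_days,
      sample_interval_ms = sample_interval_ms,
      lights_on = lights_on, lights_off = lights_off,
      start = start, tz = tz,
      baseline_level = baseline_level, drift_amplitude = drift_amplitude,
      noise_sd = noise_sd, profiles = profiles,
      bout_duration_s = bout_duration_s, bout_amplitude = bout_amplitude,
      monitor_id = as.integer(monitor_id), seed = seed
    ),
    class = "flic_sim_params"
  )
}

normalize_profiles <- function(spec, n_wells) {
  as_pair <- function(p) {
    if (inherits(p, "flic_rate_profile")) return(list(ld = p, dd = p))
    if (is.list(p) && inherits(p$ld %||% p$dd, "flic_rate_profile")) {
      return(list(ld = p$ld %||% p$dd, dd = p$dd %||% p$ld))
    }
    abort("Each bout-rate entry must be a rate profile or list(ld =, dd =).")
  }
  if (inherits(spec, "flic_rate_profile")) {
    return(rep(list(as_pair(spec)), n_wells))
  }
  if (is.list(spec) && !is.null(spec$ld %||% spec$dd)) {
    return(rep(list(as_pair(spec)), n_wells))
  }
  if (is.list(spec)) {
    if (length(spec) != n_wells) {
      abort("`bout_rate_profile` list must have one entry per well.")
    }
    return(lapply(spec, as_pair))
  }
  abort("Invalid `bout_rate_profile`.")
}

# Inhomogeneous Poisson bout onsets on [0, total_h) hours by thinning
# against the profile's maximum rate, then exponential durations and
# sequential removal of overlapping bouts.
simulate_well_bouts <- function(pair, n_ld_days, total_h, bout_duration_s,
                                sample_interval_ms) {
  segments <- list(
    list(profile = pair$ld, from_h = 0, to_h = min(n_ld_days * 24, total_h)),
    list(profile = pair$dd, from_h = min(n_ld_days * 24, total_h), to_h = total_h)
  )
  onsets <- numeric(0)
  for (seg in segments) {
    len_h <- seg$to_h - seg$from_h
    if (len_h <= 0) next
    grid <- seq(0, 24, by = 0.005)
    lambda_max <- max(rate_profile(seg$profile, grid)) * 1.001
    if (lambda_max <= 0) next
    n_cand <- rpois(1, lambda_max * len_h)
    if (n_cand == 0) next
    t_cand <- sort(runif(n_cand, seg$from_h, seg$to_h))
    accept <- runif(n_cand) < rate_profile(seg$profile, t_cand) / lambda_max
    onsets <- c(onsets, t_cand[accept])
  }
  if (length(onsets) == 0) {
    return(tibble(onset_ms = numeric(0), end_ms = numeric(0)))
  }
  onset_ms <- onsets * 3.6e6
  dur_ms <- pmax(rexp(length(onset_ms), rate = 1 / bout_duration_s) * 1000,
                 sample_interval_ms)
  end_ms <- pmin(onset_ms + dur_ms, total_h * 3.6e6)
  # enforce non-overlap: keep a bout only if it starts after the previous end
  keep <- logical(length(onset_ms))
  last_end <- -Inf
  for (i in seq_along(onset_ms)) {
    if (onset_ms[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- end_ms[i]
    }
  }
  tibble(onset_ms = onset_ms[keep], end_ms = end_ms[keep])
}

# Slow sensor drift: Gaussian random walk on hourly knots (increment sd
# chosen so one day of increments has sd `amplitude_per_day`), interpolated
# with a natural spline, so all drift power sits at timescales > 1 h.
simulate_drift <- function(times_ms, amplitude_per_day) {
  if (amplitude_per_day == 0) return(numeric(length(times_ms)))
  total_h <- max(times_ms) / 3.6e6
  knots_h <- seq(0, ceiling(total_h) + 1, by = 1)
  walk <- cumsum(c(0, rnorm(length(knots_h) - 1, 0, amplitude_per_day / sqrt(24))))
  spline(x = knots_h * 3.6e6, y = walk, xout = times_ms)$y
}

#' Simulate a FLIC experiment with known ground truth
#'
#' Generates a raw signal table indistinguishable in format from a real
#' recording, together with the ground-truth bout list used to build it.
#' The signal model is `baseline_level + drift + bout plateau + noise`,
#' quantised to integer a.u.; bouts are rectangular plateaus of
#' `bout_amplitude` drawn from an inhomogeneous Poisson process with the
#' configured rate profile.
#'
#' @param params A [simulation_params()] object.
#' @return A list of class `flic_simulation` with elements `signals` (a
#'   `flic_raw` tibble) and `truth` (a `flic_truth` tibble with columns
#'   `monitor`, `well`, `onset_ms`, `end_ms`).
#' @export
#' @examples
#' sim <- simulate_experiment(simulation_params(
#'   n_wells = 2, n_ld_days = 0, n_dd_days = 1, duration_days = 0.05,
#'   sample_interval_ms = 1000, seed = 1
#' ))
#' sim$signals
simulate_experiment <- function(params) {
  stopifnot(inherits(params, "flic_sim_params"))
  run <- function() simulate_experiment_impl(params)
  if (!is.null(params$seed)) {
    withr::with_seed(params$seed, run())
  } else {
    run()
  }
}

simulate_experiment_impl <- function(params) {
  interval <- params$sample_interval_ms
  n <- floor(params$duration_days * 86400 * 1000 / interval)
  if (n < 1) abort("Experiment too short for even one sample.")
  times_ms <- (seq_len(n) - 1) * interval
  total_h <- n * interval / 3.6e6

  dialect <- flic_dialect(
    well_columns = paste0("W", seq_len(params$n_wells)),
    sample_interval_ms = interval
  )

  wells <- vector("list", params$n_wells)
  truth <- vector("list", params$n_wells)
  for (w in seq_len(params$n_wells)) {
    bouts <- simulate_well_bouts(
      params$profiles[[w]], params$n_ld_days, total_h,
      params$bout_duration_s, interval
    )
    plateau <- numeric(n)
    if (nrow(bouts) > 0) {
      i0 <- pmin(floor(bouts$onset_ms / interval) + 1L, n)
      i1 <- pmin(ceiling(bouts$end_ms / interval), n)
      i1 <- pmax(i1, i0)
      for (b in seq_along(i0)) plateau[i0[b]:i1[b]] <- 1
    }
    drift <- simulate_drift(times_ms, params$drift_amplitude)
    noise <- if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd) else 0
    wells[[w]] <- round(params$baseline_level + drift +
                          params$bout_amplitude * plateau + noise)
    truth[[w]] <- mutate(bouts, monitor = params$monitor_id, well = w,
                         .before = 1)
  }
  names(wells) <- dialect$well_columns

  signals <- tibble(
    monitor = rep(params$monitor_id, n),
    time_ms = times_ms,
    datetime = params$start + times_ms / 1000
  )
  signals <- dplyr::bind_cols(signals, as_tibble(wells))
  signals <- new_flic_signal(signals, dialect, "flic_raw")

  truth <- dplyr::bind_rows(truth)
  truth <- structure(truth, params = params,
                     class = c("flic_truth", class(tibble())))
  structure(list(signals = signals, truth = truth), class = "flic_simulation")
}

#' @export
print.flic_simulation <- function(x, ...) {
  cat("<flic_simulation> ", ncol(x$signals) - 3, " wells, ",
      nrow(x$signals), " samples, ", nrow(x$truth),
      " ground-truth bouts\n", sep = "")
  invisible(x)
}
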