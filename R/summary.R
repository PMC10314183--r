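# Event summaries ------------------------------------------------------------

binned_attrs <- function(x) {
  list(
    interval_minutes = attr(x, "interval_minutes"),
    func = attr(x, "func"),
    normalized = attr(x, "normalized") %||% FALSE,
    norm_mode = attr(x, "norm_mode"),
    origin = attr(x, "origin"),
    sample_interval_ms = attr(x, "sample_interval_ms")
  )
}

new_flic_binned <- function(df, interval_minutes, func, origin,
                            sample_interval_ms, normalized = FALSE,
                            norm_mode = NA_character_) {
  structure(
    as_tibble(df),
    interval_minutes = interval_minutes, func = func, origin = origin,
    sample_interval_ms = sample_interval_ms,
    normalized = normalized, norm_mode = norm_mode,
    class = c("flic_binned", class(tibble()))
  )
}

#' Bin feeding events on a regular grid
#'
#' Counts event onsets per well in half-open bins `[start, start + interval)`
#' anchored at the midnight preceding the recording start. `"sum"` reports
#' the raw count per bin; `"mean"` divides the count by the nominal number
#' of samples per bin, i.e. a per-sample event rate. The grid covers the
#' whole recording span, so inactive stretches appear as zero bins.
#'
#' @param events A `flic_events` tibble (see [call_all_events()]).
#' @param interval_minutes Bin width in minutes; must divide 24 h evenly.
#'   1-minute bins are intended for short (< 1 day) recordings; on longer
#'   spans they mostly add noise, and a warning says so.
#' @param func `"sum"` or `"mean"`.
#' @return A `flic_binned` tibble with columns `monitor`, `well`,
#'   `condition`, `bin_start` (POSIXct), `value`.
#' @export
bin_events <- function(events, interval_minutes = 60,
                       func = c("sum", "mean")) {
  func <- match.arg(func)
  if (interval_minutes <= 0 || (1440 %% interval_minutes) != 0) {
    abort("`interval_minutes` must be positive and divide 24 h evenly.")
  }
  span_start <- attr(events, "span_start")
  span_end <- attr(events, "span_end")
  if (is.null(span_start) || is.na(span_start)) {
    abort("Event table lacks a recording span; produce it with call_all_events().")
  }
  tz <- attr(span_start, "tzone") %||% "UTC"
  span_days <- as.numeric(difftime(span_end, span_start, units = "days"))
  if (interval_minutes <= 1 && span_days > 1) {
    warn("1-minute bins on a multi-day recording mostly add noise; meant for < 1 day.")
  }
  origin <- as.POSIXct(format(span_start, "%Y-%m-%d"), tz = tz)
  width_s <- interval_minutes * 60
  n_bins <- ceiling((as.numeric(span_end) - as.numeric(origin)) / width_s)
  n_bins <- max(n_bins, 1)

  if (nrow(events) > 0) {
    if (any(events$onset < span_start) || any(events$onset > span_end)) {
      abort("Events fall outside the recording span; upstream inconsistency.")
    }
  }

  wells <- events_wells(events)
  grid <- tidyr::expand_grid(
    wells,
    bin_index = seq_len(n_bins) - 1L
  )
  counts <- as_tibble(events) |>
    mutate(bin_index = floor((as.numeric(.data$onset) - as.numeric(origin)) /
                               width_s)) |>
    dplyr::count(.data$monitor, .data$well, .data$bin_index)
  out <- grid |>
    left_join(counts, by = c("monitor", "well", "bin_index")) |>
    mutate(
      value = as.numeric(dplyr::coalesce(.data$n, 0L)),
      bin_start = origin + .data$bin_index * width_s
    ) |>
    select("monitor", "well", "condition", "bin_start", "value") |>
    arrange(.data$monitor, .data$well, .data$bin_start)

  interval_ms <- attr(events, "sample_interval_ms") %||% 200
  if (func == "mean") {
    out$value <- out$value / (interval_minutes * 60000 / interval_ms)
  }
  new_flic_binned(out, interval_minutes, func, origin, interval_ms)
}

#' Normalise binned series within each well
#'
#' `mode = "sum"` divides each well's bins by the well's total, so active
#' wells sum to one and flies with different appetites become comparable;
#' `mode = "max"` scales to the well's highest bin. Once normalised, the
#' series is used by the downstream profile and circadian stages as-is
#' (normalisation is inherited). Wells with zero total stay all-zero and
#' are reported in a warning.
#'
#' @param binned A `flic_binned` tibble.
#' @param mode `"sum"` or `"max"`.
#' @return The normalised `flic_binned` tibble.
#' @export
normalize_wells <- function(binned, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  a <- binned_attrs(binned)
  if (isTRUE(a$normalized)) {
    abort("Series is already normalised; refusing to normalise twice.")
  }
  out <- binned |>
    group_by(.data$monitor, .data$well) |>
    mutate(.denom = if (mode == "sum") sum(.data$value) else
      if (all(.data$value == 0)) 0 else max(.data$value)) |>
    ungroup()
  zero <- out |>
    filter(.data$.denom == 0) |>
    dplyr::distinct(.data$monitor, .data$well)
  if (nrow(zero) > 0) {
    warn(paste0("Wells with zero total left at zero: ",
                paste(paste(zero$monitor, zero$well), collapse = "; "),
                " (monitor well)."))
  }
  out <- out |>
    mutate(value = ifelse(.data$.denom > 0, .data$value / .data$.denom, 0)) |>
    select(-".denom")
  new_flic_binned(out, a$interval_minutes, a$func, a$origin,
                  a$sample_interval_ms, normalized = TRUE, norm_mode = mode)
}

#' Total feeding events per well
#'
#' One row per non-excluded well over the full loaded span; wells with no
#' events report zero.
#'
#' @param events A `flic_events` tibble.
#' @return A tibble with columns `monitor`, `well`, `condition`, `total`.
#' @export
individual_totals <- function(events) {
  wells <- events_wells(events)
  counts <- as_tibble(events) |>
    dplyr::count(.data$monitor, .data$well, name = "total")
  wells |>
    left_join(counts, by = c("monitor", "well")) |>
    mutate(total = dplyr::coalesce(.data$total, 0L)) |>
    arrange(.data$monitor, .data$well)
}

#' Group statistics of a per-well statistic
#'
#' Mean, sample standard deviation (n - 1 denominator) and standard error
#' of the mean per condition. With a single well in a condition, SD and SEM
#' are reported as missing.
#'
#' @param totals A per-well table, e.g. from [individual_totals()], with a
#'   `condition` column.
#' @param value Name of the value column (default `"total"`).
#' @return A tibble with columns `condition`, `n`, `mean`, `sd`, `sem`.
#' @export
group_stats <- function(totals, value = "total") {
  if (!value %in% names(totals)) {
    abort(paste0("Column '", value, "' not found."))
  }
  totals |>
    group_by(.data$condition) |>
    summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      sd = if (dplyr::n() >= 2) stats::sd(.data[[value]]) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(sem = .data$sd / sqrt(.data$n))
}

#' Feeding events per calendar day
#'
#' Midnight-to-midnight daily counts per well, the view used to screen for
#' flies that died mid-experiment (a dead fly's counts collapse after the
#' day it died). Every (well, day) combination within the loaded span is
#' reported, zeros included.
#'
#' @param events A `flic_events` tibble.
#' @return A tibble with columns `monitor`, `well`, `condition`, `day`
#'   (Date), `n`.
#' @export
events_per_day <- function(events) {
  span_start <- attr(events, "span_start")
  span_end <- attr(events, "span_end")
  tz <- attr(span_start, "tzone") %||% "UTC"
  days <- seq(as.Date(span_start, tz = tz), as.Date(span_end, tz = tz), by = "day")
  wells <- events_wells(events)
  counts <- as_tibble(events) |>
    mutate(day = as.Date(.data$onset, tz = tz)) |>
    dplyr::count(.data$monitor, .data$well, .data$day)
  tidyr::expand_grid(wells, day = days) |>
    left_join(counts, by = c("monitor", "well", "day")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    arrange(.data$monitor, .data$well, .data$day)
}

#' Flag outlier wells within each condition
#'
#' Tukey's boxplot rule on a per-well statistic: within each condition with
#' at least four wells, values outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are flagged, with quartiles computed as
#' Tukey hinges (medians of the lower/upper halves), matching boxplot
#' whisker convention. Conditions with fewer than four wells yield no
#' flags.
#'
#' @param totals A per-well table with a `condition` column.
#' @param value Name of the value column.
#' @return A tibble of flagged wells: `monitor`, `well`, `condition` and
#'   the value column (zero rows when nothing is flagged).
#' @export
flag_outliers <- function(totals, value = "total") {
  totals |>
    group_by(.data$condition) |>
    filter(dplyr::n() >= 4) |>
    filter({
      fn <- fivenum(.data[[value]])
      iqr <- fn[4] - fn[2]
      .data[[value]] < fn[2] - 1.5 * iqr | .data[[value]] > fn[4] + 1.5 * iqr
    }) |>
    ungroup() |>
    select("monitor", "well", "condition", dplyr::all_of(value))
}

#' Split events into day and night counts
#'
#' An event belongs to the day when its onset's time of day falls in
#' `[lights_on, lights_off)`, else to the night; day + night equals the
#' total for every well. The split is computed over the complete loaded
#' span without distinguishing LD from DD days, so trim the data first when
#' only one lighting regime is wanted.
#'
#' @param events A `flic_events` tibble.
#' @param schedule A [light_schedule()].
#' @return A tibble with columns `monitor`, `well`, `condition`, `day`,
#'   `night`.
#' @export
split_day_night <- function(events, schedule = light_schedule()) {
  stopifnot(inherits(schedule, "flic_light_schedule"))
  wells <- events_wells(events)
  if (nrow(events) == 0) {
    return(mutate(wells, day = 0L, night = 0L))
  }
  tz <- attr(events$onset, "tzone") %||% "UTC"
  tod_s <- as.numeric(events$onset) -
    as.numeric(as.POSIXct(format(events$onset, "%Y-%m-%d", tz = tz), tz = tz))
  is_day <- is_daytime(tod_s, schedule)
  counts <- as_tibble(events) |>
    mutate(.is_day = is_day) |>
    group_by(.data$monitor, .data$well) |>
    summarise(day = sum(.data$.is_day), night = sum(!.data$.is_day),
              .groups = "drop")
  wells |>
    left_join(counts, by = c("monitor", "well")) |>
    mutate(day = dplyr::coalesce(.data$day, 0L),
           night = dplyr::coalesce(.data$night, 0L)) |>
    arrange(.data$monitor, .data$well)
}

#' Average daily activity profile per condition
#'
#' Folds a binned series onto one 24 h cycle: for each time-of-day bin the
#' values of every complete recorded day of every well in a condition are
#' pooled and averaged. Partial days (before the first or after the last
#' midnight-aligned full day) are excluded. Error bars are the SEM or SD
#' over the pooled (well, day) observations; with a single observation the
#' error is missing.
#'
#' @param binned A `flic_binned` tibble spanning at least one full day.
#' @param error_bar `"SEM"`, `"SD"` or `"none"`.
#' @return A tibble with columns `condition`, `tod_h` (time of day of the
#'   bin start, hours), `mean`, `error`, `n`.
#' @export
daily_profile <- function(binned, error_bar = c("SEM", "SD", "none")) {
  error_bar <- match.arg(error_bar)
  a <- binned_attrs(binned)
  bins_per_day <- as.integer(1440 / a$interval_minutes)
  tz <- attr(binned$bin_start, "tzone") %||% "UTC"
  df <- binned |>
    mutate(day = as.Date(.data$bin_start, tz = tz))
  full_days <- df |>
    dplyr::count(.data$monitor, .data$well, .data$day) |>
    filter(.data$n == bins_per_day)
  if (nrow(full_days) == 0) {
    abort(paste0(
      "The series does not cover one full day; use the binned view instead ",
      "of a daily profile."
    ))
  }
  df <- df |>
    dplyr::semi_join(full_days, by = c("monitor", "well", "day")) |>
    mutate(tod_h = (as.numeric(.data$bin_start) -
                      as.numeric(as.POSIXct(format(.data$bin_start, "%Y-%m-%d",
                                                   tz = tz), tz = tz))) / 3600)
  df |>
    group_by(.data$condition, .data$tod_h) |>
    summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      .sd = if (dplyr::n() >= 2) stats::sd(.data$value) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(error = switch(error_bar,
                          SEM = .data$.sd / sqrt(.data$n),
                          SD = .data$.sd,
                          none = NA_real_)) |>
    select("condition", "tod_h", "mean", "error", "n") |>
    arrange(.data$condition, .data$tod_h)
}
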