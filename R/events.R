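#' Event-calling parameters
#'
#' The four FLIC parameters that turn a baselined signal into feeding
#' events:
#'
#' * `feeding_minimum` — minimum baselined value for a sample to count as an
#'   interaction (a fly touching the food).
#' * `feeding_threshold` — value a run of consecutive interactions must pass
#'   for the run to count as feeding rather than tasting.
#' * `consecutive_licks` — minimum run length, in samples.
#' * `gap` — maximum separation below which consecutive feeding events are
#'   merged into one ("link"). Given either in seconds (`"1.0 s"` or a bare
#'   number) or in samples (`"5 samples"`); the sample form matches the
#'   original FLIC convention.
#'
#' `threshold_mode` fixes the reading of "pass the threshold": `"peak"`
#' (default) requires at least one sample of the run to reach
#' `feeding_threshold`; `"all"` requires every sample to. Both comparisons
#' are inclusive (`>=`), so ties behave deterministically.
#'
#' Defaults are the worked-example settings for a standard board: minimum 5,
#' threshold 15, 2 consecutive licks, gap 5 samples. In practice these are
#' tuned per monitor.
#'
#' @param feeding_minimum,feeding_threshold Thresholds in baselined a.u.;
#'   `feeding_minimum <= feeding_threshold`.
#' @param consecutive_licks Minimum run length in samples (>= 1).
#' @param gap Merge distance: a number (seconds) or a string with an
#'   explicit unit, `"<x> s"` or `"<x> samples"`.
#' @param threshold_mode `"peak"` or `"all"`.
#' @return A `flic_event_params` object.
#' @export
#' @examples
#' event_params(5, 15, 2, gap = "5 samples")
event_params <- function(feeding_minimum = 5, feeding_threshold = 15,
                         consecutive_licks = 2, gap = "5 samples",
                         threshold_mode = c("peak", "all")) {
  threshold_mode <- match.arg(threshold_mode)
  if (feeding_minimum > feeding_threshold) {
    abort("`feeding_minimum` must not exceed `feeding_threshold`.")
  }
  if (consecutive_licks < 1) abort("`consecutive_licks` must be >= 1.")
  g <- parse_gap(gap)
  structure(
    list(feeding_minimum = feeding_minimum,
         feeding_threshold = feeding_threshold,
         consecutive_licks = as.integer(consecutive_licks),
         gap_value = g$value, gap_unit = g$unit,
         threshold_mode = threshold_mode),
    class = "flic_event_params"
  )
}

parse_gap <- function(gap) {
  if (is.numeric(gap)) {
    if (gap < 0) abort("`gap` must be >= 0.")
    return(list(value = gap, unit = "s"))
  }
  m <- regmatches(gap, regexec(
    "^\\s*([0-9]*\\.?[0-9]+)\\s*(s|sec|secs|seconds|sample|samples)\\s*$", gap
  ))[[1]]
  if (length(m) != 3) {
    abort(paste0("Cannot parse `gap` = '", gap,
                 "'; use e.g. \"1.0 s\" or \"5 samples\"."))
  }
  value <- as.numeric(m[2])
  unit <- if (startsWith(m[3], "s") && !startsWith(m[3], "sa")) "s" else "samples"
  list(value = value, unit = unit)
}

gap_in_ms <- function(params, sample_interval_ms) {
  if (params$gap_unit == "samples") {
    params$gap_value * sample_interval_ms
  } else {
    params$gap_value * 1000
  }
}

#' @export
print.flic_event_params <- function(x, ...) {
  cat("<flic_event_params> minimum ", x$feeding_minimum,
      ", threshold ", x$feeding_threshold, " (", x$threshold_mode, ")",
      ", consecutive licks ", x$consecutive_licks,
      ", gap ", x$gap_value, " ", x$gap_unit, "\n", sep = "")
  invisible(x)
}

# Core caller on one numeric series. Steps:
#  1. mark interaction samples (value >= feeding_minimum),
#  2. run-length encode maximal interaction runs,
#  3. qualify runs: length >= consecutive_licks and threshold reached
#     (peak: run maximum; all: every sample),
#  4. merge qualified events separated by <= gap.
# Returns a tibble of onset/end sample times plus internal per-event
# microstructure (lick count, peak) that downstream summaries ignore.
call_events_core <- function(x, times, minimum, threshold, licks, gap_ms,
                             mode) {
  n <- length(x)
  empty <- list(onset_ms = numeric(0), end_ms = numeric(0),
                n_licks = integer(0), peak = numeric(0))
  if (n == 0) return(empty)
  if (!all(is.finite(x))) abort("Baselined signal contains non-finite values.")
  inter <- x >= minimum
  r <- rle(inter)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= licks
  starts <- starts[ok]
  ends <- ends[ok]
  if (length(starts) == 0) return(empty)
  qual <- logical(length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:ends[i]]
    qual[i] <- if (mode == "peak") max(seg) >= threshold else min(seg) >= threshold
  }
  starts <- starts[qual]
  ends <- ends[qual]
  if (length(starts) == 0) return(empty)
  if (length(starts) > 1) {
    sep <- times[starts[-1]] - times[ends[-length(ends)]]
    grp <- cumsum(c(1L, as.integer(sep > gap_ms)))
  } else {
    grp <- 1L
  }
  first_i <- which(!duplicated(grp))
  last_i <- c(first_i[-1] - 1L, length(grp))
  onset_idx <- starts[first_i]
  end_idx <- ends[last_i]
  n_grp <- length(first_i)
  peak <- numeric(n_grp)
  licks_n <- integer(n_grp)
  for (g in seq_len(n_grp)) {
    runs <- first_i[g]:last_i[g]
    peak[g] <- max(x[onset_idx[g]:end_idx[g]])
    licks_n[g] <- sum(ends[runs] - starts[runs] + 1L)
  }
  list(
    onset_ms = as.numeric(times[onset_idx]),
    end_ms = as.numeric(times[end_idx]),
    n_licks = licks_n,
    peak = peak
  )
}

events_core_tibble <- function(core) {
  new_tibble(core, nrow = length(core$onset_ms))
}

#' Call feeding events on one baselined series
#'
#' Applies the four-parameter FLIC criterion (see [event_params()]) to one
#' well: interaction samples are run-length encoded, runs are qualified by
#' length and threshold, and qualified events closer together than the gap
#' are merged. A merged event's onset is the first constituent's onset.
#'
#' @param baselined Numeric vector of baselined readings.
#' @param times Sample times in ms; defaults to a regular grid at
#'   `sample_interval_ms`.
#' @param params A [event_params()] object.
#' @param sample_interval_ms Milliseconds between samples (used for the
#'   default `times` and for gaps given in samples).
#' @return A tibble with one row per event: `onset_ms`, `end_ms`,
#'   `n_licks`, `peak`.
#' @export
#' @examples
#' call_feeding_events(c(6, 16, 16, 6), params = event_params(5, 15, 2, "5 samples"),
#'                     sample_interval_ms = 200)
call_feeding_events <- function(baselined, times = NULL,
                                params = event_params(),
                                sample_interval_ms = 200) {
  stopifnot(inherits(params, "flic_event_params"))
  times <- times %||% ((seq_along(baselined) - 1) * sample_interval_ms)
  if (length(times) != length(baselined)) {
    abort("`times` and `baselined` must have the same length.")
  }
  events_core_tibble(call_events_core(
    baselined, times,
    params$feeding_minimum, params$feeding_threshold,
    params$consecutive_licks, gap_in_ms(params, sample_interval_ms),
    params$threshold_mode
  ))
}

#' Call feeding events for every well of a baselined table
#'
#' @param x A `flic_baselined` table.
#' @param params A [event_params()] object.
#' @param conditions Optional [assign_conditions()] map; labels are attached
#'   to events and wells marked excluded there are dropped up front.
#' @param quiet Suppress the per-well event-count message.
#' @return A `flic_events` tibble with columns `monitor`, `well`,
#'   `condition`, `onset`, `onset_ms`, `end_ms`, `n_licks`, `peak`, sorted
#'   by well then onset. The table carries the well universe and recording
#'   span as attributes so that wells without any event still appear in
#'   downstream summaries.
#' @export
call_all_events <- function(x, params = event_params(), conditions = NULL,
                            quiet = FALSE) {
  stopifnot(inherits(params, "flic_event_params"))
  dialect <- signal_dialect(x)
  interval <- dialect$sample_interval_ms
  monitor <- if (nrow(x) > 0) x$monitor[1] else NA_integer_
  wells_universe <- conditions %||% assign_conditions(
    monitors = unique(x$monitor), n_wells = length(dialect$well_columns)
  )

  rows <- vector("list", length(dialect$well_columns))
  counts <- integer(length(dialect$well_columns))
  for (w in seq_along(dialect$well_columns)) {
    col <- dialect$well_columns[w]
    ev <- tryCatch(
      events_core_tibble(call_events_core(
        as.numeric(x[[col]]), x$time_ms,
        params$feeding_minimum, params$feeding_threshold,
        params$consecutive_licks, gap_in_ms(params, interval),
        params$threshold_mode
      )),
      error = function(e) abort(paste0("Well ", col, ": ", conditionMessage(e)))
    )
    counts[w] <- nrow(ev)
    rows[[w]] <- mutate(ev, monitor = monitor, well = w, .before = 1)
  }
  if (!quiet) {
    inform(paste0("Events per well: ",
                  paste(dialect$well_columns, counts, sep = "=",
                        collapse = ", ")))
  }
  out <- dplyr::bind_rows(rows)
  origin <- if (nrow(x) > 0) x$datetime[1] else NA
  out <- out |>
    left_join(select(as_tibble(wells_universe), "monitor", "well", "condition"),
              by = c("monitor", "well")) |>
    mutate(onset = origin + .data$onset_ms / 1000, .after = "condition") |>
    arrange(.data$well, .data$onset_ms)

  wu <- as_tibble(wells_universe)
  excluded0 <- if ("excluded" %in% names(wu)) wu[wu$excluded, ] else wu[0, ]
  out <- structure(
    out,
    wells = as_tibble(wells_universe)[c("monitor", "well", "condition")],
    span_start = if (nrow(x) > 0) min(x$datetime) else NA,
    span_end = if (nrow(x) > 0) max(x$datetime) else NA,
    sample_interval_ms = interval,
    class = c("flic_events", class(tibble()))
  )
  if (nrow(excluded0) > 0) {
    out <- exclude_wells(out, excluded0[c("monitor", "well")])
  }
  out
}

#' Drop excluded wells from an event table
#'
#' Removes all events of the given wells and shrinks the well universe so
#' the exclusion propagates to every downstream summary and periodogram.
#' Typically used after inspecting individual statistics for dead flies or
#' outliers.
#'
#' @param events A `flic_events` tibble.
#' @param exclude A data frame with columns `monitor`, `well`, or a list of
#'   `c(monitor, well)` pairs.
#' @return The filtered `flic_events` tibble.
#' @export
exclude_wells <- function(events, exclude) {
  exc <- normalize_exclude_spec(exclude)
  wells <- attr(events, "wells")
  key_all <- paste(wells$monitor, wells$well)
  key_exc <- paste(exc$monitor, exc$well)
  unknown <- setdiff(key_exc, key_all)
  if (length(unknown) > 0) {
    warn(paste0("Ignoring unknown wells in exclusion set: ",
                paste(unknown, collapse = "; "), " (monitor well)."))
  }
  keep_rows <- !(paste(events$monitor, events$well) %in% key_exc)
  out <- events[keep_rows, , drop = FALSE]
  attr(out, "wells") <- wells[!(key_all %in% key_exc), , drop = FALSE]
  attr(out, "span_start") <- attr(events, "span_start")
  attr(out, "span_end") <- attr(events, "span_end")
  attr(out, "sample_interval_ms") <- attr(events, "sample_interval_ms")
  class(out) <- class(events)
  out
}

events_wells <- function(events) {
  attr(events, "wells") %||%
    dplyr::distinct(as_tibble(events)[c("monitor", "well", "condition")])
}
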