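#' Describe the CSV layout written by a FLIC monitor
#'
#' A FLIC Drosophila Feeding Monitor (DFM) streams one CSV per monitor with a
#' sample counter, a wall-clock date and time, a millisecond counter and one
#' integer capacitance column per well. Firmware revisions differ in column
#' names and clock formats, so the reader is parameterised by a dialect
#' object rather than hard-coding one layout. The default dialect is:
#' columns `Sample, Date, Time, MSec, W1..W12`, dates as `MM/DD/YYYY`,
#' clock as `HH:MM:SS`, `MSec` counting milliseconds since recording start,
#' and a nominal 200 ms (5 Hz) sample interval.
#'
#' @param well_columns Character vector of well column names, in well order.
#'   A standard DFM has exactly 12 wells; other counts are accepted to
#'   support partial or simulated boards.
#' @param time_column Name of the millisecond-counter column.
#' @param date_column,clock_column Names of the wall-clock date and
#'   time-of-day columns.
#' @param datetime_format `strptime()` format used to parse the
#'   concatenation of the date and clock columns.
#' @param monitor_pattern Regular expression whose first capture group is the
#'   monitor number, applied to the file name. The default takes the first
#'   integer following a "DFM" token; if it does not match, the first integer
#'   anywhere in the file name is used as a fallback.
#' @param sample_interval_ms Nominal milliseconds between samples; must be
#'   positive.
#'
#' @return An object of class `flic_dialect`.
#' @export
#' @examples
#' d <- flic_dialect()
#' d$well_columns
flic_dialect <- function(well_columns = paste0("W", 1:12),
                         time_column = "MSec",
                         date_column = "Date",
                         clock_column = "Time",
                         datetime_format = "%m/%d/%Y %H:%M:%S",
                         monitor_pattern = "[Dd][Ff][Mm][_ -]*([0-9]+)",
                         sample_interval_ms = 200) {
  if (length(well_columns) < 1 || anyDuplicated(well_columns)) {
    abort("`well_columns` must be a non-empty set of distinct column names.")
  }
  if (!is.numeric(sample_interval_ms) || sample_interval_ms <= 0) {
    abort("`sample_interval_ms` must be > 0.")
  }
  structure(
    list(
      well_columns = as.character(well_columns),
      time_column = time_column,
      date_column = date_column,
      clock_column = clock_column,
      datetime_format = datetime_format,
      monitor_pattern = monitor_pattern,
      sample_interval_ms = as.numeric(sample_interval_ms)
    ),
    class = "flic_dialect"
  )
}

#' @export
print.flic_dialect <- function(x, ...) {
  cat("<flic_dialect>\n")
  cat("  wells:          ", paste(x$well_columns, collapse = ", "), "\n")
  cat("  time column:    ", x$time_column, "\n")
  cat("  datetime:       ", x$date_column, "+", x$clock_column,
      " (", x$datetime_format, ")\n", sep = "")
  cat("  sample interval:", x$sample_interval_ms, "ms\n")
  invisible(x)
}

#' Extract the monitor number from a FLIC file name
#'
#' Monitor identity is conventionally encoded in the file name (for example
#' `DFM_1_2021-07-01.csv` is monitor 1). Parsing is deterministic: the same
#' file name always yields the same monitor number.
#'
#' @param path File path or name.
#' @param pattern Regular expression with the monitor number as its first
#'   capture group (see [flic_dialect()]).
#' @return A single integer monitor id.
#' @export
#' @examples
#' monitor_from_filename("DFM_1_2021-07-01.csv")
monitor_from_filename <- function(path, pattern = flic_dialect()$monitor_pattern) {
  fname <- basename(path)
  m <- regexec(pattern, fname)[[1]]
  if (m[1] != -1L && length(m) >= 2L) {
    return(as.integer(regmatches(fname, list(m))[[1]][2]))
  }
  # fallback: first integer anywhere in the file name
  m2 <- regmatches(fname, regexpr("[0-9]+", fname))
  if (length(m2) == 1L) {
    return(as.integer(m2))
  }
  abort(paste0(
    "Cannot extract a monitor number from '", fname,
    "'. Pass an explicit `monitor_id` to override filename parsing."
  ))
}

#' Define the light schedule of an experiment
#'
#' Day is the half-open interval `[lights_on, lights_off)`; an event whose
#' onset falls exactly at lights-off belongs to the night. Schedules that
#' wrap midnight (lights on in the evening) are supported.
#'
#' @param lights_on,lights_off Times of day as `"HH:MM"` or `"HH:MM:SS"`
#'   strings, or numeric hours. They must differ.
#' @return An object of class `flic_light_schedule` with `on_s` and `off_s`
#'   (seconds after midnight).
#' @export
#' @examples
#' light_schedule("09:00", "21:00")
light_schedule <- function(lights_on = "09:00:00", lights_off = "21:00:00") {
  on_s <- parse_time_of_day(lights_on)
  off_s <- parse_time_of_day(lights_off)
  if (on_s == off_s) {
    abort("`lights_on` and `lights_off` must differ.")
  }
  structure(list(on_s = on_s, off_s = off_s), class = "flic_light_schedule")
}

#' @export
print.flic_light_schedule <- function(x, ...) {
  fmt <- function(s) sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
  cat("<flic_light_schedule> lights on ", fmt(x$on_s),
      ", lights off ", fmt(x$off_s), "\n", sep = "")
  invisible(x)
}

# seconds after midnight from "HH:MM[:SS]" or numeric hours
parse_time_of_day <- function(x) {
  if (is.numeric(x)) {
    if (x < 0 || x >= 24) abort("time of day in hours must be in [0, 24)")
    return(round(x * 3600))
  }
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (!length(parts) %in% 2:3 || anyNA(suppressWarnings(as.numeric(parts)))) {
    abort(paste0("Cannot parse time of day: '", x, "' (expected HH:MM[:SS])."))
  }
  parts <- as.numeric(parts)
  s <- parts[1] * 3600 + parts[2] * 60 + if (length(parts) == 3) parts[3] else 0
  if (s < 0 || s >= 86400) abort("time of day must fall within one day")
  s
}

# TRUE where time-of-day (seconds after midnight) falls in the light phase
is_daytime <- function(tod_s, schedule) {
  stopifnot(inherits(schedule, "flic_light_schedule"))
  if (schedule$on_s < schedule$off_s) {
    tod_s >= schedule$on_s & tod_s < schedule$off_s
  } else {
    tod_s >= schedule$on_s | tod_s < schedule$off_s
  }
}
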