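# Internal constructor for wide signal tables (raw or baselined).
# Columns: monitor, time_ms (ms since first sample of that monitor),
# datetime (POSIXct), then one column per well. Well columns keep the
# dialect's names; well index is the position within `dialect$well_columns`.
new_flic_signal <- function(df, dialect, subclass) {
  df <- as_tibble(df)
  structure(
    df,
    dialect = dialect,
    class = c(subclass, class(tibble()))
  )
}

signal_dialect <- function(x) {
  attr(x, "dialect") %||% flic_dialect()
}

#' Well columns of a signal table
#'
#' @param x A `flic_raw` or `flic_baselined` table.
#' @return Character vector of well column names in well order.
#' @export
well_columns <- function(x) {
  signal_dialect(x)$well_columns
}

#' Read a raw FLIC monitor CSV
#'
#' Reads one original, unedited CSV file streamed by a FLIC monitor into a
#' validated signal table. The monitor number is parsed from the file name
#' (see [monitor_from_filename()]); timestamps are converted to milliseconds
#' since the first sample, and the wall-clock origin of the recording is
#' stored in the `datetime` column.
#'
#' @param path Path to the CSV file.
#' @param dialect A [flic_dialect()] describing the column layout.
#' @param monitor_id Optional explicit monitor number, overriding filename
#'   parsing.
#' @param tz Time zone of the wall-clock columns.
#' @return A `flic_raw` tibble with columns `monitor`, `time_ms`, `datetime`
#'   and one column per well.
#' @export
read_flic_csv <- function(path, dialect = flic_dialect(), monitor_id = NULL,
                          tz = "UTC") {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  needed <- c(dialect$time_column, dialect$date_column, dialect$clock_column,
              dialect$well_columns)
  missing_cols <- setdiff(needed, names(df))
  missing_wells <- intersect(missing_cols, dialect$well_columns)
  if (length(missing_wells) > 0) {
    abort(paste0(
      "FLIC format error in '", basename(path), "': missing well column(s) ",
      paste(missing_wells, collapse = ", "), "."
    ))
  }
  if (length(missing_cols) > 0) {
    abort(paste0(
      "FLIC format error in '", basename(path), "': missing column(s) ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }

  monitor_id <- monitor_id %||% monitor_from_filename(path, dialect$monitor_pattern)

  t_raw <- as.numeric(df[[dialect$time_column]])
  if (length(t_raw) > 1 && any(diff(t_raw) <= 0)) {
    bad <- which(diff(t_raw) <= 0)[1] + 1L
    abort(paste0(
      "Timestamps are not strictly increasing in '", basename(path),
      "' (first offending row: ", bad, ")."
    ))
  }

  if (nrow(df) > 0) {
    origin <- as.POSIXct(
      paste(df[[dialect$date_column]][1], df[[dialect$clock_column]][1]),
      format = dialect$datetime_format, tz = tz
    )
    if (is.na(origin)) {
      abort(paste0(
        "Cannot parse wall-clock origin from '", basename(path),
        "' with format '", dialect$datetime_format, "'."
      ))
    }
    time_ms <- t_raw - t_raw[1]
    datetime <- origin + time_ms / 1000
  } else {
    time_ms <- numeric(0)
    datetime <- as.POSIXct(numeric(0), origin = "1970-01-01", tz = tz)
  }

  wells <- df[dialect$well_columns]
  wells[] <- lapply(wells, as.numeric)

  out <- tibble(
    monitor = rep(as.integer(monitor_id), nrow(df)),
    time_ms = time_ms,
    datetime = datetime
  )
  out <- dplyr::bind_cols(out, wells)
  new_flic_signal(out, dialect, "flic_raw")
}

#' Read and concatenate several CSV files from one monitor
#'
#' Long recordings are often split across files. Files are ordered by their
#' wall-clock origin and concatenated; overlapping time ranges raise an
#' error. All files must share the monitor number.
#'
#' @inheritParams read_flic_csv
#' @param paths Character vector of CSV paths.
#' @return A single `flic_raw` tibble; `time_ms` counts from the first
#'   sample of the earliest file.
#' @export
read_flic_monitor <- function(paths, dialect = flic_dialect(),
                              monitor_id = NULL, tz = "UTC") {
  tabs <- lapply(paths, read_flic_csv, dialect = dialect,
                 monitor_id = monitor_id, tz = tz)
  tabs <- tabs[order(vapply(
    tabs, function(t) as.numeric(t$datetime[1] %||% Inf), numeric(1)
  ))]
  ids <- unique(vapply(tabs, function(t) t$monitor[1] %||% NA_integer_, integer(1)))
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1) {
    abort(paste0("Files belong to different monitors: ",
                 paste(ids, collapse = ", ")))
  }
  for (i in seq_along(tabs)[-1]) {
    prev_end <- max(tabs[[i - 1]]$datetime)
    if (nrow(tabs[[i]]) > 0 && tabs[[i]]$datetime[1] <= prev_end) {
      abort("Files overlap in time; refusing to concatenate.")
    }
  }
  out <- dplyr::bind_rows(tabs)
  if (nrow(out) > 0) {
    out$time_ms <- as.numeric(difftime(out$datetime, out$datetime[1], units = "secs")) * 1000
  }
  new_flic_signal(out, dialect, "flic_raw")
}

#' Trim a signal table to a window of calendar dates
#'
#' Trimming is whole-day inclusive on both ends: a sample is kept when its
#' wall-clock date `d` satisfies `start <= d <= end`. Trimming operates on
#' the raw (or baselined) data, before any downstream stage.
#'
#' @param x A `flic_raw` or `flic_baselined` table.
#' @param start,end First and last calendar date to keep (anything
#'   `as.Date()` accepts).
#' @return The trimmed table, same class and attributes.
#' @export
trim_by_date <- function(x, start, end) {
  stopifnot(is.data.frame(x), "datetime" %in% names(x))
  start <- as.Date(start)
  end <- as.Date(end)
  if (start > end) abort("`start` must not be after `end`.")
  d <- as.Date(x$datetime, tz = attr(x$datetime, "tzone") %||% "UTC")
  keep <- !is.na(d) & d >= start & d <= end
  out <- x[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warn("Date trimming removed every sample; the result is empty.")
  }
  subclass <- setdiff(class(x), class(tibble()))
  new_flic_signal(out, signal_dialect(x),
                  if (length(subclass)) subclass[1] else "flic_raw")
}

#' Write a signal table as a FLIC-dialect CSV
#'
#' Emits the same column layout the monitor firmware writes
#' (`Sample, Date, Time, MSec, W1..`), so simulated recordings round-trip
#' through [read_flic_csv()].
#'
#' @param x A `flic_raw` table.
#' @param path Output path. To make filename-based monitor parsing work,
#'   include the monitor number after a `DFM` token, e.g. `DFM_1.csv`.
#' @return `path`, invisibly.
#' @export
write_flic_csv <- function(x, path) {
  dialect <- signal_dialect(x)
  tz <- attr(x$datetime, "tzone") %||% "UTC"
  out <- tibble(
    Sample = seq_len(nrow(x)),
    Date = format(x$datetime, "%m/%d/%Y", tz = tz),
    Time = format(x$datetime, "%H:%M:%S", tz = tz),
    MSec = as.numeric(x$time_ms)
  )
  names(out)[names(out) == "Date"] <- dialect$date_column
  names(out)[names(out) == "Time"] <- dialect$clock_column
  names(out)[names(out) == "MSec"] <- dialect$time_column
  out <- dplyr::bind_cols(out, x[dialect$well_columns])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write an output table as CSV
#'
#' All downstream tables (events, individual and group statistics, binned
#' series, day/night splits, periodogram summaries) are written as RFC-4180
#' CSV with a header row. Floating-point values are written at 6 significant
#' digits, so a write/read round trip is lossless at that precision.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  if (is.null(x)) abort("`x` must be a table, not NULL.")
  x <- as_tibble(as.data.frame(x))
  is_dbl <- vapply(x, function(col) {
    is.double(col) && !inherits(col, "POSIXct") && !inherits(col, "Date")
  }, logical(1))
  x[is_dbl] <- lapply(x[is_dbl], signif, digits = 6)
  is_dt <- vapply(x, inherits, logical(1), what = "POSIXct")
  x[is_dt] <- lapply(x[is_dt], function(col) {
    format(col, "%Y-%m-%dT%H:%M:%OS3", tz = attr(col, "tzone") %||% "UTC")
  })
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
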