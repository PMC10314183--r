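# Autocorrelation periodogram ------------------------------------------------
#
# Rhythmicity of feeding is assessed under constant darkness (DD). For a
# binned event series x_1..x_N the power at candidate period k * delta is
# the autocorrelation coefficient
#
#   r_k = sum_{t <= N-k} (x_t - xbar)(x_{t+k} - xbar) / sum_t (x_t - xbar)^2
#
# (exactly what stats::acf computes). The peak of r_k over the period range
# estimates the free-running period; its height measures rhythm strength.
# Significance uses the large-lag white-noise normal approximation: under
# an arrhythmic null r_k is approximately N(0, 1/N), giving the one-sided
# per-lag threshold z_{1-alpha}/sqrt(N) (rhythm = positive autocorrelation)
# and the peak p-value 1 - Phi(r_peak * sqrt(N)). The threshold is per lag:
# the maximum over many lags of a null series exceeds it more often than
# alpha, so judge group rhythmicity on the condition-average periodogram
# rather than on single-well peaks near the line.

#' Autocorrelation periodogram of one binned series
#'
#' @param x Numeric vector: one well's binned event series restricted to
#'   the DD window, on a regular grid.
#' @param bin_interval_minutes Bin width of `x`, in minutes.
#' @param period_range_h Two-element numeric, the candidate period range in
#'   hours (default 16-32 h, covering the circadian band).
#' @param alpha Significance level for the per-lag threshold.
#' @return A list with elements `periodogram` (tibble `period_h`, `power`),
#'   `peak_period_h`, `peak_power`, `p_value`, `signif_threshold` and `n`
#'   (series length). Ties at the peak resolve to the smallest period.
#' @export
#' @examples
#' x <- cos(2 * pi * seq(0, 96, by = 0.5) / 24)[-1]
#' ac_periodogram(x, 30)$peak_period_h
ac_periodogram <- function(x, bin_interval_minutes = 30,
                           period_range_h = c(16, 32), alpha = 0.05) {
  if (length(period_range_h) != 2 || period_range_h[1] >= period_range_h[2]) {
    abort("`period_range_h` must be (min, max) with min < max.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  n <- length(x)
  delta_h <- bin_interval_minutes / 60
  k_min <- ceiling(period_range_h[1] / delta_h)
  k_max <- floor(period_range_h[2] / delta_h)
  n_required <- ceiling(2 * period_range_h[2] / delta_h)
  if (n < n_required) {
    abort(paste0("Series too short for periods up to ", period_range_h[2],
                 " h: need at least ", n_required, " bins, got ", n, "."))
  }
  if (var(x) == 0) {
    abort("Constant series has no rhythm estimate (zero variance).")
  }
  r <- as.numeric(acf(x, lag.max = k_max, plot = FALSE,
                      demean = TRUE)$acf)
  stopifnot(abs(r[1] - 1) < 1e-10)  # r_0 = 1 by construction
  lags <- k_min:k_max
  power <- r[lags + 1]
  periods <- lags * delta_h
  peak_i <- which.max(power)  # ties: first = smallest period
  signif_threshold <- qnorm(1 - alpha) / sqrt(n)
  p_value <- max(1 - pnorm(power[peak_i] * sqrt(n)), .Machine$double.eps)
  list(
    periodogram = tibble(period_h = periods, power = power),
    peak_period_h = periods[peak_i],
    peak_power = power[peak_i],
    p_value = p_value,
    signif_threshold = signif_threshold,
    n = n
  )
}

#' Periodograms for every well of a binned series
#'
#' Restricts the binned series to the constant-darkness window (whole-day
#' inclusive, the same convention as [trim_by_date()]), then computes one
#' autocorrelation periodogram per well. Short DD windows give unstable
#' period estimates; below five days a warning recommends extending the
#' recording. Constant (zero-variance) wells cannot be scored and are
#' dropped with a warning naming them.
#'
#' @param binned A `flic_binned` tibble (typically 30-min bins, as counted
#'   or normalised upstream).
#' @param dd_start,dd_end First and last calendar date of the DD window;
#'   `NULL` uses the full series.
#' @param period_range_h Candidate period range in hours.
#' @param alpha Significance level.
#' @return A `flic_periodogram` object: list with `curves` (long tibble
#'   `monitor`, `well`, `condition`, `period_h`, `power`), `peaks` (one row
#'   per well: `peak_period_h`, `peak_power`, `p_value`,
#'   `signif_threshold`, `n_bins`), and the parameters used.
#' @export
periodogram <- function(binned, dd_start = NULL, dd_end = NULL,
                        period_range_h = c(16, 32), alpha = 0.05) {
  a <- binned_attrs(binned)
  tz <- attr(binned$bin_start, "tzone") %||% "UTC"
  df <- as_tibble(binned)
  if (!is.null(dd_start) || !is.null(dd_end)) {
    d <- as.Date(df$bin_start, tz = tz)
    dd_start <- as.Date(dd_start %||% min(d))
    dd_end <- as.Date(dd_end %||% max(d))
    if (dd_start > dd_end) abort("`dd_start` must not be after `dd_end`.")
    if (dd_start < min(d) || dd_end > max(d)) {
      abort("DD window extends beyond the loaded span.")
    }
    df <- df[d >= dd_start & d <= dd_end, , drop = FALSE]
    if (as.numeric(dd_end - dd_start) + 1 < 5) {
      warn("DD window shorter than 5 days; period estimates may be unstable.")
    }
  }
  if (nrow(df) == 0) abort("No bins fall inside the DD window.")

  wells <- dplyr::distinct(df[c("monitor", "well", "condition")])
  curves <- vector("list", nrow(wells))
  peaks <- vector("list", nrow(wells))
  dropped <- character(0)
  for (i in seq_len(nrow(wells))) {
    sub <- df |>
      filter(.data$monitor == wells$monitor[i], .data$well == wells$well[i]) |>
      arrange(.data$bin_start)
    res <- tryCatch(
      ac_periodogram(sub$value, a$interval_minutes, period_range_h, alpha),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (grepl("zero variance", conditionMessage(res))) {
        dropped <- c(dropped, paste(wells$monitor[i], wells$well[i]))
        next
      }
      abort(paste0("Monitor ", wells$monitor[i], " well ", wells$well[i],
                   ": ", conditionMessage(res)))
    }
    curves[[i]] <- mutate(res$periodogram,
                          monitor = wells$monitor[i], well = wells$well[i],
                          condition = wells$condition[i], .before = 1)
    peaks[[i]] <- tibble(
      monitor = wells$monitor[i], well = wells$well[i],
      condition = wells$condition[i],
      peak_period_h = res$peak_period_h, peak_power = res$peak_power,
      p_value = res$p_value, signif_threshold = res$signif_threshold,
      n_bins = res$n
    )
  }
  if (length(dropped) > 0) {
    warn(paste0("Dropped constant (zero-variance) wells: ",
                paste(dropped, collapse = "; "), " (monitor well)."))
  }
  structure(
    list(
      curves = dplyr::bind_rows(curves),
      peaks = dplyr::bind_rows(peaks),
      alpha = alpha, period_range_h = period_range_h,
      dd_start = dd_start, dd_end = dd_end,
      bin_interval_minutes = a$interval_minutes
    ),
    class = "flic_periodogram"
  )
}

#' @export
print.flic_periodogram <- function(x, ...) {
  cat("<flic_periodogram> ", nrow(x$peaks), " wells, periods ",
      x$period_range_h[1], "-", x$period_range_h[2], " h, alpha ",
      x$alpha, "\n", sep = "")
  print(x$peaks)
  invisible(x)
}

#' Condition-level summary of a periodogram fit
#'
#' Produces the per-well summary table (peak period, peak power, p-value,
#' significance threshold, with Tukey-fence outlier flags on peak power
#' within each condition) and the condition-average periodogram with SEM,
#' the curve on which group rhythmicity is judged.
#'
#' @param pg A `flic_periodogram`.
#' @return A `flic_periodogram_summary`: list with `table` (per-well rows
#'   plus `outlier` flag) and `mean_curve` (`condition`, `period_h`,
#'   `mean_power`, `sem`, `n`).
#' @export
periodogram_summary <- function(pg) {
  stopifnot(inherits(pg, "flic_periodogram"))
  flagged <- flag_outliers(pg$peaks, value = "peak_power")
  key <- paste(flagged$monitor, flagged$well)
  table <- pg$peaks |>
    mutate(outlier = paste(.data$monitor, .data$well) %in% key)
  mean_curve <- pg$curves |>
    group_by(.data$condition, .data$period_h) |>
    summarise(
      n = dplyr::n(),
      mean_power = mean(.data$power),
      sem = if (dplyr::n() >= 2) stats::sd(.data$power) / sqrt(dplyr::n())
            else NA_real_,
      .groups = "drop"
    )
  structure(
    list(table = table, mean_curve = mean_curve, alpha = pg$alpha,
         signif_threshold = if (nrow(pg$peaks)) pg$peaks$signif_threshold[1]
                            else NA_real_),
    class = "flic_periodogram_summary"
  )
}

#' @export
print.flic_periodogram_summary <- function(x, ...) {
  cat("<flic_periodogram_summary>\n")
  print(x$table)
  invisible(x)
}

#' @rdname periodogram
#' @param x A `flic_periodogram`.
#' @param ... Unused.
#' @method tidy flic_periodogram
#' @export
tidy.flic_periodogram <- function(x, ...) {
  x$peaks
}

#' @rdname periodogram
#' @method glance flic_periodogram
#' @export
glance.flic_periodogram <- function(x, ...) {
  tibble(
    n_wells = nrow(x$peaks),
    alpha = x$alpha,
    signif_threshold = if (nrow(x$peaks)) x$peaks$signif_threshold[1] else NA_real_,
    n_significant = sum(x$peaks$peak_power > x$peaks$signif_threshold),
    median_peak_period_h = median(x$peaks$peak_period_h),
    mean_peak_power = mean(x$peaks$peak_power)
  )
}
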