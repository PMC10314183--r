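# Baseline estimation --------------------------------------------------------
#
# Capacitance readings drift slowly (humidity, food level, temperature);
# feeding contacts ride on top as short positive deflections. Baselining
# estimates the drifting floor and subtracts it, leaving deflections near a
# zero baseline where the event thresholds apply.

# Running-median baseline estimate. Window is specified in minutes and
# converted to an odd sample count (round half up); edges use the truncated
# centred window, which avoids phantom deflections at recording boundaries.
rm_baseline_estimate <- function(signal, window_minutes, sample_interval_ms) {
  n <- length(signal)
  if (n == 0) return(numeric(0))
  k <- max(1, round(window_minutes * 60000 / sample_interval_ms))
  if (k %% 2 == 0) k <- k + 1
  h <- (k - 1) / 2
  if (k >= n) {
    return(vapply(seq_len(n), function(i) {
      median(signal[max(1, i - h):min(n, i + h)])
    }, numeric(1)))
  }
  base <- as.numeric(runmed(signal, k, endrule = "keep"))
  if (h > 0) {
    edge <- seq_len(h)
    base[edge] <- vapply(edge, function(i) {
      median(signal[1:min(n, i + h)])
    }, numeric(1))
    edge2 <- (n - h + 1):n
    base[edge2] <- vapply(edge2, function(i) {
      median(signal[max(1, i - h):n])
    }, numeric(1))
  }
  base
}

#' Running-median baselining of one well
#'
#' Subtracts the median of a centred moving window from each sample. The
#' window is given in minutes (default 5) and converted to an odd sample
#' count; near the recording edges the window is truncated. Exactly
#' invariant to adding a constant to the signal.
#'
#' @param signal Numeric vector of raw capacitance readings.
#' @param window_minutes Moving-window width in minutes.
#' @param sample_interval_ms Milliseconds between samples.
#' @return `signal` minus its running-median baseline.
#' @export
#' @examples
#' running_median_baseline(c(0, 0, 10, 0, 0), window_minutes = 3 * 200 / 60000,
#'                         sample_interval_ms = 200)
running_median_baseline <- function(signal, window_minutes = 5,
                                    sample_interval_ms = 200) {
  if (window_minutes <= 0) abort("`window_minutes` must be > 0.")
  if (length(signal) && !all(is.finite(signal))) {
    abort("Signal contains non-finite values.")
  }
  signal - rm_baseline_estimate(signal, window_minutes, sample_interval_ms)
}

# One asymmetric-least-squares fit: penalised weighted least squares with
# a squared-second-difference roughness penalty (Whittaker smoother) and
# asymmetric residual weights p (above baseline) / 1 - p (below), iterated
# to a fixed point of the weights.
als_baseline_estimate <- function(signal, lambda, p, max_iter, tol) {
  n <- length(signal)
  # centre the signal: the smoother is shift-equivariant, and solving at a
  # small signal scale keeps the ill-conditioned system's forward error
  # (which grows with lambda) independent of the sensor's absolute level
  mu <- mean(signal)
  signal <- signal - mu
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2),
                                           rep(-2, n - 2),
                                           rep(1, n - 2)))
  C <- lambda * Matrix::crossprod(D)
  # residuals smaller than this count as "on the baseline"; without it,
  # floating-point noise on flat stretches makes the weight signs oscillate
  tie_eps <- 1e-6 * max(1, diff(range(signal)))
  w <- rep(1, n)
  z <- signal
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    A <- C + Matrix::Diagonal(n, x = w)
    f <- Matrix::Cholesky(A, LDL = FALSE)
    b <- w * signal
    z <- as.numeric(Matrix::solve(f, b, system = "A"))
    # two steps of iterative refinement: the system's conditioning grows
    # with lambda, and downstream contracts are tighter than a single
    # solve delivers
    for (ref in 1:2) {
      r <- b - as.numeric(A %*% z)
      z <- z + as.numeric(Matrix::solve(f, r, system = "A"))
    }
    w_new <- ifelse(signal - z > tie_eps, p, 1 - p)
    if (sum(abs(w_new - w)) <= tol * n) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  if (!converged) {
    warn(paste0("ALS weights did not stabilise within ", max_iter,
                " iterations; returning the last iterate."))
  }
  z + mu
}

#' Asymmetric-least-squares baselining of one well
#'
#' Fits a Whittaker-smoothed baseline `z` minimising
#' `sum(w * (y - z)^2) + lambda * sum(diff(z, differences = 2)^2)` with
#' asymmetric weights `w = p` where `y > z` and `1 - p` elsewhere, iterated
#' until the weights stop changing. The strong asymmetry (`p` small) keeps
#' the baseline pinned under feeding peaks, so deflections survive
#' subtraction. Requires no per-recording tuning, which is its advantage
#' over the running median.
#'
#' @param signal Numeric vector of raw capacitance readings (length >= 3).
#' @param lambda Roughness penalty; larger is smoother. The default (1e8)
#'   is referenced to 5 Hz sampling; see [als_lambda_default()] for other
#'   sampling rates.
#' @param p Asymmetry weight in (0, 1).
#' @param max_iter Maximum weight iterations.
#' @param tol Convergence tolerance on the mean absolute weight change
#'   (0 demands an exact fixed point).
#' @return `signal` minus the fitted baseline.
#' @export
als_baseline <- function(signal, lambda = 1e8, p = 0.01, max_iter = 20,
                         tol = 0) {
  if (length(signal) < 3) abort("ALS needs a series of length >= 3.")
  if (!all(is.finite(signal))) abort("Signal contains non-finite values.")
  if (lambda <= 0) abort("`lambda` must be > 0.")
  if (p <= 0 || p >= 1) abort("`p` must lie in (0, 1).")
  signal - als_baseline_estimate(signal, lambda, p, max_iter, tol)
}

#' Default ALS roughness penalty for a sampling rate
#'
#' The roughness penalty acts on per-sample second differences, so the
#' penalty that yields a given smoothing timescale scales with the fourth
#' power of the sampling rate. The reference value is 1e8 at the nominal
#' 200 ms (5 Hz) FLIC interval.
#'
#' @param sample_interval_ms Milliseconds between samples.
#' @return A lambda value.
#' @export
als_lambda_default <- function(sample_interval_ms = 200) {
  1e8 * (200 / sample_interval_ms)^4
}

# Chunked application of a baseline estimator with cross-faded overlaps.
# Full-recording ALS systems grow large, so estimation runs on chunks
# (default 24 h). Each chunk is extended by 2x the overlap: the outer half
# is a discarded margin that absorbs the estimator's boundary effects
# (window truncation for RM, smoother edge conditions for ALS), the inner
# half is a linear cross-fade between neighbouring chunks. Within the
# cross-fade both chunks see the estimator's full context, so for a local
# estimator like the running median the chunked result equals the
# unchunked one exactly.
chunked_baseline <- function(signal, chunk_samples, overlap_samples, estimator) {
  n <- length(signal)
  if (n == 0) return(numeric(0))
  if (n <= chunk_samples) return(estimator(signal))
  ov <- overlap_samples
  starts <- seq(1, n, by = chunk_samples)
  num <- numeric(n)
  den <- numeric(n)
  for (s in starts) {
    e <- min(s + chunk_samples - 1, n)
    ext_s <- max(1, s - 2 * ov)
    ext_e <- min(n, e + 2 * ov)
    z <- estimator(signal[ext_s:ext_e])
    pos <- ext_s:ext_e
    wgt <- numeric(length(pos))
    wgt[pos >= s & pos <= e] <- 1
    left <- pos >= s - ov & pos < s
    wgt[left] <- (pos[left] - (s - ov) + 1) / (ov + 1)
    right <- pos > e & pos <= e + ov
    wgt[right] <- ((e + ov) - pos[right] + 1) / (ov + 1)
    if (s == min(starts)) wgt[pos < s] <- 0  # no left neighbour exists
    num[pos] <- num[pos] + wgt * z
    den[pos] <- den[pos] + wgt
  }
  num / den
}

#' Baseline every well of a raw signal table
#'
#' Applies the selected baseline method per well, processing long
#' recordings in chunks whose overlaps are cross-faded (chunking is an
#' implementation detail; its seams are contractually artifact-free).
#' Baselined values may be negative; they are not clipped.
#'
#' @param x A `flic_raw` table.
#' @param method `"rm"` (running median) or `"als"` (asymmetric least
#'   squares).
#' @param rm_window_minutes Running-median window, minutes.
#' @param als_lambda,als_p,als_max_iter,als_tol ALS parameters; a `NULL`
#'   `als_lambda` selects [als_lambda_default()] for the table's sampling
#'   interval.
#' @param chunk_hours Processing chunk length in hours.
#' @return A `flic_baselined` table with the same shape, timestamps and
#'   attributes as `x`.
#' @export
baseline_table <- function(x, method = c("rm", "als"),
                           rm_window_minutes = 5,
                           als_lambda = NULL, als_p = 0.01,
                           als_max_iter = 20, als_tol = 0,
                           chunk_hours = 24) {
  method <- match.arg(method)
  dialect <- signal_dialect(x)
  interval <- dialect$sample_interval_ms
  if (chunk_hours <= 0) abort("`chunk_hours` must be > 0.")
  if (rm_window_minutes <= 0) abort("`rm_window_minutes` must be > 0.")
  als_lambda <- als_lambda %||% als_lambda_default(interval)

  estimator <- if (method == "rm") {
    function(y) rm_baseline_estimate(y, rm_window_minutes, interval)
  } else {
    function(y) als_baseline_estimate(y, als_lambda, als_p, als_max_iter, als_tol)
  }
  overlap_ms <- if (method == "rm") rm_window_minutes * 60000 else 10 * 60000
  overlap_samples <- ceiling(overlap_ms / interval)
  chunk_samples <- max(round(chunk_hours * 3.6e6 / interval),
                       2 * overlap_samples + 1)

  out <- x
  for (col in dialect$well_columns) {
    y <- as.numeric(x[[col]])
    if (length(y) && !all(is.finite(y))) {
      abort(paste0("Well ", col, ": signal contains non-finite values."))
    }
    res <- tryCatch(
      y - chunked_baseline(y, chunk_samples, overlap_samples, estimator),
      error = function(e) {
        abort(paste0("Well ", col, ": ", conditionMessage(e)))
      }
    )
    out[[col]] <- res
  }
  out <- new_flic_signal(out, dialect, "flic_baselined")
  attr(out, "baseline_method") <- method
  out
}

#' Quick-look binning of baselined samples
#'
#' Aggregates baselined samples of each well into consecutive bins for QC
#' visualisation (this binning is for graphing only; event binning happens
#' downstream of event calling). A recording shorter than one interval
#' yields a single bin.
#'
#' @param x A `flic_baselined` (or `flic_raw`) table.
#' @param interval_minutes Bin width in minutes (default one hour).
#' @param func Aggregation, `"sum"` or `"mean"` (default sum).
#' @return A tibble with columns `monitor`, `well`, `bin_start_ms`, `value`.
#' @export
binned_preview <- function(x, interval_minutes = 60, func = c("sum", "mean")) {
  func <- match.arg(func)
  if (interval_minutes <= 0) abort("`interval_minutes` must be > 0.")
  dialect <- signal_dialect(x)
  width_ms <- interval_minutes * 60000
  long <- x |>
    tidyr::pivot_longer(dplyr::all_of(dialect$well_columns),
                        names_to = "well_name", values_to = "value") |>
    mutate(well = match(.data$well_name, dialect$well_columns),
           bin_start_ms = floor(.data$time_ms / width_ms) * width_ms)
  agg <- if (func == "sum") sum else mean
  long |>
    group_by(.data$monitor, .data$well, .data$bin_start_ms) |>
    summarise(value = agg(.data$value), .groups = "drop") |>
    arrange(.data$monitor, .data$well, .data$bin_start_ms)
}
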