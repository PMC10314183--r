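# Independent reference implementations used as oracles. They share no code
# with the package internals: runs are found by an explicit element-wise
# scan, merging is done by repeated pairwise passes to a fixed point, and
# the ALS oracle solves the penalised system with dense base-R linear
# algebra.

# Brute-force feeding-event enumerator on one series (times in ms).
brute_force_events <- function(x, times, minimum, threshold, licks, gap_ms,
                               mode = "peak") {
  n <- length(x)
  events <- list()
  i <- 1
  while (i <= n) {
    if (x[i] >= minimum) {
      j <- i
      while (j < n && x[j + 1] >= minimum) j <- j + 1
      run <- x[i:j]
      long_enough <- (j - i + 1) >= licks
      passes <- if (mode == "peak") any(run >= threshold) else all(run >= threshold)
      if (long_enough && passes) {
        events[[length(events) + 1]] <- c(start = i, end = j)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(events) == 0) {
    return(data.frame(onset_ms = numeric(0), end_ms = numeric(0)))
  }
  ev <- do.call(rbind, events)
  # merge to a fixed point by repeated pairwise passes
  repeat {
    merged_any <- FALSE
    k <- 1
    out <- list()
    while (k <= nrow(ev)) {
      cur <- ev[k, ]
      while (k < nrow(ev) &&
             times[ev[k + 1, "start"]] - times[cur["end"]] <= gap_ms) {
        cur["end"] <- ev[k + 1, "end"]
        k <- k + 1
        merged_any <- TRUE
      }
      out[[length(out) + 1]] <- cur
      k <- k + 1
    }
    ev <- do.call(rbind, out)
    if (!merged_any) break
  }
  data.frame(onset_ms = times[ev[, "start"]], end_ms = times[ev[, "end"]])
}

# Dense-matrix ALS oracle: identical objective and tie rule, but direct
# base-R LU solves with iterative refinement instead of sparse Cholesky.
dense_als_estimate <- function(y, lambda, p, max_iter = 20) {
  n <- length(y)
  mu <- mean(y)
  y <- y - mu
  D <- diff(diag(n), differences = 2)
  C <- lambda * t(D) %*% D
  tie_eps <- 1e-6 * max(1, diff(range(y)))
  w <- rep(1, n)
  z <- y
  for (iter in seq_len(max_iter)) {
    A <- C + diag(w)
    b <- w * y
    z <- solve(A, b)
    for (ref in 1:2) z <- z + solve(A, b - A %*% z)
    z <- as.numeric(z)
    w_new <- ifelse(y - z > tie_eps, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  as.numeric(z) + mu
}

# Direct truncated-centred-window running median.
direct_running_median <- function(x, k) {
  n <- length(x)
  h <- (k - 1) / 2
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# Match detected event onsets against ground-truth bout onsets: a detection
# is a true positive when it starts within `tol_ms` of an unmatched truth
# bout. Returns recall and precision.
match_events_to_truth <- function(detected_onsets, truth_onsets, tol_ms) {
  used <- rep(FALSE, length(truth_onsets))
  tp <- 0
  for (o in detected_onsets) {
    d <- abs(truth_onsets - o)
    d[used] <- Inf
    if (length(d) && min(d) <= tol_ms) {
      used[which.min(d)] <- TRUE
      tp <- tp + 1
    }
  }
  list(
    recall = if (length(truth_onsets)) tp / length(truth_onsets) else NA_real_,
    precision = if (length(detected_onsets)) tp / length(detected_onsets)
                else NA_real_
  )
}

# Small simulated experiment used by several tests.
small_simulation <- function(seed = 42, n_wells = 4, days = 1,
                             interval_ms = 1000,
                             profile = rate_flat(6)) {
  simulate_experiment(simulation_params(
    n_wells = n_wells, n_ld_days = 0, n_dd_days = days,
    duration_days = days, sample_interval_ms = interval_ms,
    bout_rate_profile = profile, bout_duration_s = 5,
    baseline_level = 100, drift_amplitude = 20, noise_sd = 2,
    bout_amplitude = 40, seed = seed
  ))
}

# Build a flic_events table directly from a simulation's ground truth,
# bypassing baselining/event calling, to exercise downstream stages alone.
structure_events_from_truth <- function(sim) {
  signals <- sim$signals
  truth <- sim$truth
  origin <- signals$datetime[1]
  wells <- tibble::tibble(
    monitor = signals$monitor[1],
    well = seq_along(well_columns(signals)),
    condition = "Condition"
  )
  ev <- tibble::as_tibble(truth)
  ev$condition <- "Condition"
  ev$onset <- origin + ev$onset_ms / 1000
  ev$n_licks <- 1L
  ev$peak <- 40
  ev <- ev[order(ev$well, ev$onset_ms),
           c("monitor", "well", "condition", "onset", "onset_ms", "end_ms",
             "n_licks", "peak")]
  # the last simulated bout can start after the final sample; real events
  # always sit on sample times, so clip to the recorded span
  ev <- ev[ev$onset <= max(signals$datetime), , drop = FALSE]
  structure(
    ev,
    wells = wells,
    span_start = min(signals$datetime),
    span_end = max(signals$datetime),
    sample_interval_ms = attr(signals, "dialect")$sample_interval_ms,
    class = c("flic_events", class(tibble::tibble()))
  )
}

# 30-min binned counts of an inhomogeneous Poisson bout process over a
# given number of days (independent of the package's simulator internals).
simulate_bouts_series <- function(profile, days, bin_min = 30) {
  total_h <- days * 24
  grid <- seq(0, 24, by = 0.005)
  lmax <- max(rate_profile(profile, grid)) * 1.001
  n_cand <- rpois(1, lmax * total_h)
  t_cand <- sort(runif(n_cand, 0, total_h))
  keep <- runif(n_cand) < rate_profile(profile, t_cand %% 24) / lmax
  onsets <- t_cand[keep]
  bins <- floor(onsets / (bin_min / 60))
  tabulate(bins + 1, nbins = total_h / (bin_min / 60))
}

# Full single-well pipeline at 1 s sampling: simulate raw signal, baseline
# with the running median, call events with the worked-example parameters,
# bin to 30 min, and return the periodogram peak row.
run_well_pipeline <- function(profile, dd_days = 4, seed = NULL) {
  sim <- simulate_experiment(simulation_params(
    n_wells = 1, n_ld_days = 0, n_dd_days = dd_days, duration_days = dd_days,
    sample_interval_ms = 1000, bout_rate_profile = profile,
    bout_duration_s = 2, seed = seed
  ))
  b <- baseline_table(sim$signals, method = "rm")
  ev <- call_all_events(b, event_params(5, 15, 2, "5 samples"), quiet = TRUE)
  binned <- bin_events(ev, 30)
  pg <- periodogram(binned)
  pg$peaks
}
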