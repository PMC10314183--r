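test_that("event parameters validate and parse gap units", {
  p <- event_params(5, 15, 2, gap = "5 samples")
  expect_identical(p$gap_unit, "samples")
  expect_equal(flicrhythm:::gap_in_ms(p, 200), 1000)
  p2 <- event_params(gap = "1.5 s")
  expect_equal(flicrhythm:::gap_in_ms(p2, 200), 1500)
  p3 <- event_params(gap = 2)
  expect_equal(flicrhythm:::gap_in_ms(p3, 200), 2000)
  expect_error(event_params(feeding_minimum = 20, feeding_threshold = 10), "exceed")
  expect_error(event_params(consecutive_licks = 0), ">= 1")
  expect_error(event_params(gap = "5 parsecs"), "gap")
})

test_that("the worked-example hand traces call the expected events", {
  p <- event_params(5, 15, 2, gap = "5 samples")
  # run [6,16,16,6]: all four samples are interactions, peak 16 >= 15 -> 1 event
  ev <- call_feeding_events(c(6, 16, 16, 6), params = p, sample_interval_ms = 200)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$onset_ms, 0)
  expect_equal(ev$end_ms, 600)
  # run [6,6,6,6] never reaches the threshold -> 0 events
  expect_identical(nrow(call_feeding_events(c(6, 6, 6, 6), params = p)), 0L)
  # all-zero series -> no events
  expect_identical(nrow(call_feeding_events(rep(0, 50), params = p)), 0L)
  # gap merging: two qualified runs 3 samples apart merge at gap 5 samples
  x <- c(6, 16, 0, 0, 0, 16, 6)
  ev2 <- call_feeding_events(x, params = p, sample_interval_ms = 200)
  expect_identical(nrow(ev2), 1L)
  expect_equal(ev2$onset_ms, 0)
  expect_equal(ev2$end_ms, 1200)
  # but not at gap 2 samples
  p2 <- event_params(5, 15, 2, gap = "2 samples")
  expect_identical(nrow(call_feeding_events(x, params = p2)), 2L)
})

test_that("threshold_mode 'all' requires every sample to pass", {
  pa <- event_params(5, 15, 2, gap = "0 samples", threshold_mode = "all")
  pp <- event_params(5, 15, 2, gap = "0 samples", threshold_mode = "peak")
  # runs: [6,16] (peak passes, 'all' fails on the 6) and [16,16] (both pass)
  x <- c(6, 16, 0, 16, 16)
  expect_identical(nrow(call_feeding_events(x, params = pa)), 1L)
  expect_identical(nrow(call_feeding_events(x, params = pp)), 2L)
})

test_that("random series match the brute-force enumerator exactly", {
  withr::with_seed(42, {
    for (i in 1:400) {
      n <- sample(1:60, 1)
      x <- sample(0:20, n, replace = TRUE)
      minimum <- sample(1:10, 1)
      threshold <- minimum + sample(0:8, 1)
      licks <- sample(1:4, 1)
      gap_samples <- sample(0:6, 1)
      mode <- sample(c("peak", "all"), 1)
      p <- event_params(minimum, threshold, licks,
                        paste(gap_samples, "samples"), mode)
      got <- call_feeding_events(x, params = p, sample_interval_ms = 200)
      want <- brute_force_events(x, (seq_len(n) - 1) * 200, minimum,
                                 threshold, licks, gap_samples * 200, mode)
      expect_equal(got$onset_ms, want$onset_ms)
      expect_equal(got$end_ms, want$end_ms)
    }
  })
})

test_that("complete small-universe sweep agrees with the enumerator", {
  # every series of length <= 7 over {0, minimum, threshold}
  minimum <- 5; threshold <- 15
  p <- event_params(minimum, threshold, 2, "1 samples")
  vals <- c(0, minimum, threshold)
  for (len in 1:7) {
    grid <- as.matrix(expand.grid(rep(list(vals), len)))
    times <- (seq_len(len) - 1) * 200
    for (r in seq_len(nrow(grid))) {
      x <- as.numeric(grid[r, ])
      got <- call_feeding_events(x, params = p, sample_interval_ms = 200)
      want <- brute_force_events(x, times, minimum, threshold, 2, 200, "peak")
      if (!isTRUE(all.equal(got$onset_ms, want$onset_ms)) ||
          !isTRUE(all.equal(got$end_ms, want$end_ms))) {
        fail(paste("Mismatch on series", paste(x, collapse = ",")))
      }
    }
  }
  succeed()
})

test_that("event counts are monotone non-increasing in the merge gap", {
  # a larger gap only coarsens the partition of qualified runs, so this
  # monotonicity is exact for arbitrary series
  withr::with_seed(9, {
    for (rep in 1:10) {
      x <- sample(0:25, 300, replace = TRUE)
      counts <- sapply(0:8, function(g) {
        nrow(call_feeding_events(
          x, params = event_params(5, 15, 2, paste(g, "samples"))
        ))
      })
      expect_true(all(diff(counts) <= 0))
    }
  })
})

test_that("stricter thresholds reduce event counts on realistic signals", {
  # On real-shaped signals (well-separated bout plateaus) stricter
  # parameters call fewer events. This is a statistical property, not an
  # algebraic one: because merging happens after qualification, removing a
  # qualified run can split a merge group, as the counterexample shows.
  sim <- small_simulation(seed = 14, n_wells = 2, days = 1)
  b <- baseline_table(sim$signals, method = "rm")
  count <- function(minimum = 5, threshold = 15, licks = 2) {
    nrow(call_all_events(b, event_params(minimum, threshold, licks,
                                         "5 samples"), quiet = TRUE))
  }
  expect_true(all(diff(sapply(c(3, 5, 10, 15), function(m)
    count(minimum = m))) <= 0))
  expect_true(all(diff(sapply(c(15, 25, 39), function(th)
    count(threshold = th))) <= 0))
  expect_true(all(diff(sapply(c(1, 2, 4), function(l)
    count(licks = l))) <= 0))

  # counterexample: raising the minimum splits one run into two events
  x <- c(15, 5, 15)
  lo <- call_feeding_events(x, params = event_params(5, 15, 1, "1 samples"))
  hi <- call_feeding_events(x, params = event_params(6, 15, 1, "1 samples"))
  expect_identical(nrow(lo), 1L)
  expect_identical(nrow(hi), 2L)
})

test_that("called events respect the separation invariant and translate with time", {
  withr::with_seed(10, {
    x <- sample(0:25, 300, replace = TRUE)
    p <- event_params(5, 15, 2, "3 samples")
    ev <- call_feeding_events(x, params = p, sample_interval_ms = 200)
    if (nrow(ev) > 1) {
      expect_true(all(ev$onset_ms[-1] - ev$end_ms[-nrow(ev)] > 3 * 200))
    }
    expect_true(all(ev$onset_ms <= ev$end_ms))
    # translation invariance
    times <- (seq_along(x) - 1) * 200
    ev2 <- call_feeding_events(x, times = times + 5000, params = p,
                               sample_interval_ms = 200)
    expect_equal(ev2$onset_ms, ev$onset_ms + 5000)
  })
})

test_that("table-level calling recovers simulated bouts with high recall and precision", {
  sim <- small_simulation(seed = 31, n_wells = 4, days = 1)
  b <- baseline_table(sim$signals, method = "rm")
  ev <- call_all_events(b, event_params(5, 15, 2, "5 samples"), quiet = TRUE)
  for (w in 1:4) {
    det <- ev$onset_ms[ev$well == w]
    tru <- sim$truth$onset_ms[sim$truth$well == w]
    m <- match_events_to_truth(det, tru, tol_ms = 5000)
    expect_gte(m$recall, 0.9)
    expect_gte(m$precision, 0.9)
  }
})

test_that("permissive parameters yield at least as many events", {
  sim <- small_simulation(seed = 32, n_wells = 2, days = 0.5)
  b <- baseline_table(sim$signals, method = "rm")
  strict <- call_all_events(b, event_params(10, 15, 2, "5 samples"), quiet = TRUE)
  permissive <- call_all_events(b, event_params(5, 15, 2, "5 samples"), quiet = TRUE)
  expect_gte(nrow(permissive), nrow(strict))
})

test_that("well exclusion removes events and propagates to summaries", {
  sim <- small_simulation(seed = 33, n_wells = 4, days = 0.5)
  b <- baseline_table(sim$signals, method = "rm")
  ev <- call_all_events(b, quiet = TRUE)

  # empty exclusion = identity
  same <- exclude_wells(ev, list(list(monitor = 99, well = 1))) |>
    suppressWarnings()
  expect_identical(nrow(same), nrow(ev))

  one_out <- exclude_wells(ev, data.frame(monitor = 1, well = 3))
  expect_identical(nrow(one_out), sum(ev$well != 3))
  expect_identical(nrow(individual_totals(one_out)), 3L)

  all_out <- exclude_wells(ev, data.frame(monitor = 1, well = 1:4))
  expect_identical(nrow(all_out), 0L)
  expect_warning(exclude_wells(ev, data.frame(monitor = 2, well = 1)),
                 "unknown")
})
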