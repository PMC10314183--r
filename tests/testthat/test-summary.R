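# A compact event table built directly (bypassing the signal pipeline) so
# summary arithmetic can be checked by hand.
make_events <- function(onsets_h_by_well, span_days = 2,
                        conditions = NULL, monitor = 1L,
                        start = "2021-07-01 00:00:00") {
  origin <- as.POSIXct(start, tz = "UTC")
  n_wells <- length(onsets_h_by_well)
  rows <- purrr::imap_dfr(onsets_h_by_well, function(on_h, w) {
    tibble::tibble(
      monitor = rep(monitor, length(on_h)), well = rep(as.integer(w), length(on_h)),
      onset_ms = on_h * 3.6e6, end_ms = on_h * 3.6e6 + 5000,
      n_licks = rep(3L, length(on_h)), peak = rep(20, length(on_h))
    )
  })
  conds <- conditions %||% rep("Condition", n_wells)
  wells <- tibble::tibble(monitor = monitor, well = seq_len(n_wells),
                          condition = conds)
  rows <- dplyr::left_join(rows, wells, by = c("monitor", "well"))
  rows$onset <- origin + rows$onset_ms / 1000
  rows <- dplyr::arrange(rows, well, onset_ms)
  structure(
    rows[c("monitor", "well", "condition", "onset", "onset_ms", "end_ms",
           "n_licks", "peak")],
    wells = wells,
    span_start = origin,
    span_end = origin + span_days * 86400 - 1,
    sample_interval_ms = 1000,
    class = c("flic_events", class(tibble::tibble()))
  )
}

test_that("event binning counts onsets on a midnight-anchored half-open grid", {
  ev <- make_events(list(c(10 / 60, 40 / 60, 1 + 10 / 60)), span_days = 2 / 24)
  b <- bin_events(ev, interval_minutes = 60)
  expect_equal(b$value, c(2, 1))
  expect_identical(format(b$bin_start[1], "%H:%M"), "00:00")

  # no events -> all-zero series over the full span
  b0 <- bin_events(make_events(list(numeric(0)), span_days = 1),
                   interval_minutes = 60)
  expect_identical(nrow(b0), 24L)
  expect_true(all(b0$value == 0))

  # mean mode divides by nominal samples per bin (1 s sampling here)
  bm <- bin_events(ev, interval_minutes = 60, func = "mean")
  expect_equal(bm$value, c(2, 1) / 3600)

  expect_error(bin_events(ev, interval_minutes = 7), "divide")
})

test_that("binning conserves the event total and an out-of-span event errors", {
  sim <- small_simulation(seed = 51, n_wells = 3, days = 2)
  b <- baseline_table(sim$signals, method = "rm")
  ev <- call_all_events(b, quiet = TRUE)
  binned <- bin_events(ev, 60)
  sums <- binned |>
    dplyr::group_by(well) |>
    dplyr::summarise(s = sum(value))
  totals <- individual_totals(ev)
  expect_equal(sums$s, as.numeric(totals$total))

  bad <- ev
  bad$onset[1] <- bad$onset[1] - 86400 * 10
  expect_error(bin_events(bad, 60), "span")
})

test_that("normalisation divides by the well total or maximum and is inheritable", {
  ev <- make_events(list(
    c(0.5, 0.6, 1.5, 1.7, 2.5, 2.6, 2.7, 2.8),  # bins 2,2,4 over 3 h
    numeric(0)
  ), span_days = 3 / 24)
  b <- bin_events(ev, 60)
  ns <- suppressWarnings(normalize_wells(b, "sum"))
  expect_equal(ns$value[ns$well == 1], c(0.25, 0.25, 0.5))
  nm <- suppressWarnings(normalize_wells(b, "max"))
  expect_equal(nm$value[nm$well == 1], c(0.5, 0.5, 1.0))

  # zero-total wells stay zero and are flagged
  expect_warning(normalize_wells(b, "sum"), "zero total")
  expect_true(all(ns$value[ns$well == 2] == 0))

  # double normalisation is refused
  expect_error(normalize_wells(ns, "sum"), "already")

  # active wells sum to exactly 1
  expect_equal(sum(ns$value[ns$well == 1]), 1)
})

test_that("normalising then binning commutes with binning then normalising (sum mode)", {
  sim <- small_simulation(seed = 52, n_wells = 2, days = 1)
  b <- baseline_table(sim$signals, method = "rm")
  ev <- call_all_events(b, quiet = TRUE)
  fine <- normalize_wells(bin_events(ev, 30), "sum")
  # re-aggregate the normalised 30-min bins to hours and compare with
  # normalising hourly bins directly
  hourly <- normalize_wells(bin_events(ev, 60), "sum")
  re <- fine |>
    dplyr::mutate(hour = as.POSIXct(trunc(bin_start, "hours"))) |>
    dplyr::group_by(well, hour) |>
    dplyr::summarise(value = sum(value), .groups = "drop")
  expect_equal(re$value, hourly$value)
})

test_that("individual totals cover all non-excluded wells including silent ones", {
  ev <- make_events(list(c(1, 2, 3), numeric(0), 5), span_days = 1)
  tot <- individual_totals(ev)
  expect_identical(nrow(tot), 3L)
  expect_equal(tot$total, c(3L, 0L, 1L))
})

test_that("group statistics use the sample SD and SEM = SD/sqrt(n)", {
  tot <- tibble::tibble(monitor = 1, well = 1:3, condition = "a",
                        total = c(10, 20, 30))
  gs <- group_stats(tot)
  expect_equal(gs$mean, 20)
  expect_equal(gs$sd, 10)
  expect_equal(gs$sem, 5.773503, tolerance = 1e-6)

  # one-well condition: SD and SEM are missing
  tot1 <- tibble::tibble(monitor = 1, well = 1, condition = "b", total = 7)
  gs1 <- group_stats(tot1)
  expect_equal(gs1$mean, 7)
  expect_true(is.na(gs1$sd) && is.na(gs1$sem))

  # equal totals: SD = SEM = 0
  tot2 <- tibble::tibble(monitor = 1, well = 1:4, condition = "c", total = 5)
  gs2 <- group_stats(tot2)
  expect_equal(gs2$sd, 0)
  expect_equal(gs2$sem, 0)
})

test_that("events per day uses calendar-day bins and conserves totals", {
  ev <- make_events(list(c(0.5, 25, 26, 49), c(1)), span_days = 7)
  epd <- events_per_day(ev)
  expect_identical(length(unique(epd$day)), 7L)
  w1 <- epd$n[epd$well == 1]
  expect_equal(w1[1:3], c(1L, 2L, 1L))
  sums <- epd |>
    dplyr::group_by(well) |>
    dplyr::summarise(s = sum(n))
  expect_equal(sums$s, individual_totals(ev)$total)
})

test_that("Tukey-fence outlier flags match the hand-computed hinges", {
  tot <- tibble::tibble(monitor = 1, well = 1:6, condition = "a",
                        total = c(10, 11, 12, 12, 13, 40))
  out <- flag_outliers(tot)
  # hinges 11 and 13, IQR 2, fences [8, 16] -> only the 40 flies out
  expect_identical(nrow(out), 1L)
  expect_identical(out$well, 6L)

  # identical totals: no flags
  same <- tibble::tibble(monitor = 1, well = 1:5, condition = "a", total = 9)
  expect_identical(nrow(flag_outliers(same)), 0L)

  # fewer than 4 wells in a condition: never flagged
  few <- tibble::tibble(monitor = 1, well = 1:3, condition = "a",
                        total = c(1, 2, 1000))
  expect_identical(nrow(flag_outliers(few)), 0L)
})

test_that("random outlier flags equal a brute-force fence evaluation", {
  withr::with_seed(53, {
    for (rep in 1:20) {
      n <- sample(4:12, 1)
      tot <- tibble::tibble(
        monitor = 1, well = seq_len(n),
        condition = sample(c("a", "b"), n, replace = TRUE),
        total = sample(0:500, n, replace = TRUE)
      )
      got <- flag_outliers(tot)
      want <- do.call(rbind, lapply(split(tot, tot$condition), function(g) {
        if (nrow(g) < 4) return(g[0, ])
        fn <- fivenum(g$total)
        iqr <- fn[4] - fn[2]
        g[g$total < fn[2] - 1.5 * iqr | g$total > fn[4] + 1.5 * iqr, ]
      }))
      expect_setequal(got$well, want$well)
    }
  })
})

test_that("day/night split follows the half-open light interval and conserves totals", {
  sched <- light_schedule("09:00", "21:00")
  ev <- make_events(list(c(10, 22, 21, 9, 8.999)), span_days = 1)
  dn <- split_day_night(ev, sched)
  # 10:00 day; 22:00 night; exactly 21:00 night; exactly 09:00 day; 08:59.6 night
  expect_equal(dn$day, 2L)
  expect_equal(dn$night, 3L)

  # empty well
  dn0 <- split_day_night(make_events(list(numeric(0))), sched)
  expect_equal(dn0$day + dn0$night, 0L)

  # random events: conservation and agreement with direct classification
  withr::with_seed(54, {
    on_h <- sort(runif(200, 0, 48))
    ev2 <- make_events(list(on_h), span_days = 2)
    dn2 <- split_day_night(ev2, sched)
    tod <- on_h %% 24
    want_day <- sum(tod >= 9 & tod < 21)
    expect_equal(dn2$day, want_day)
    expect_equal(dn2$day + dn2$night, 200L)
  })

  # wrap-around schedule (lights on at night)
  swrap <- light_schedule("21:00", "09:00")
  dnw <- split_day_night(ev, swrap)
  expect_equal(dnw$day, 3L)
})

test_that("daily profiles average complete days and report the chosen error bar", {
  # one well, two days, hourly bins [1,3] then [3,5] in the first two hours
  ev <- make_events(list(c(
    rep(0.5, 1), rep(1.5, 3),        # day 1: bins 1, 3
    rep(24.5, 3), rep(25.5, 5)       # day 2: bins 3, 5
  )), span_days = 2)
  b <- bin_events(ev, 60)
  pr <- daily_profile(b, "SEM")
  expect_equal(pr$mean[pr$tod_h == 0], 2)
  expect_equal(pr$mean[pr$tod_h == 1], 4)
  expect_equal(pr$error[pr$tod_h == 0], 1)
  expect_equal(pr$error[pr$tod_h == 1], 1)

  # a perfectly periodic series has zero error bars
  ev2 <- make_events(list(c(0.5, 5.5, 24.5, 29.5)), span_days = 2)
  pr2 <- daily_profile(bin_events(ev2, 60), "SD")
  expect_true(all(pr2$error == 0))

  # single full day: profile equals that day, error missing
  ev3 <- make_events(list(c(0.5, 5.5)), span_days = 1)
  pr3 <- daily_profile(bin_events(ev3, 60), "SEM")
  expect_equal(pr3$mean[pr3$tod_h == 0], 1)
  expect_true(all(is.na(pr3$error)))

  # less than one full day is an error pointing at the binned view
  ev4 <- make_events(list(c(0.5)), span_days = 0.5)
  expect_error(daily_profile(bin_events(ev4, 60), "SEM"), "full day")
})

test_that("simulated bimodal wells peak at the light transitions in the profile", {
  sim <- simulate_experiment(simulation_params(
    n_wells = 2, n_ld_days = 2, n_dd_days = 0, duration_days = 2,
    sample_interval_ms = 1000,
    bout_rate_profile = rate_bimodal(2, 30, 0.75), seed = 55
  ))
  b <- baseline_table(sim$signals, method = "rm")
  ev <- call_all_events(b, quiet = TRUE)
  pr <- daily_profile(bin_events(ev, 60), "SEM")
  morning <- pr[pr$tod_h >= 5 & pr$tod_h <= 13, ]
  evening <- pr[pr$tod_h >= 17 | pr$tod_h <= 1, ]
  expect_lte(abs(morning$tod_h[which.max(morning$mean)] - 9), 1)
  expect_lte(abs(evening$tod_h[which.max(evening$mean)] - 21), 1)
})
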