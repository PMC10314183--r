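test_that("running median: constant signals baseline to exactly zero", {
  x <- rep(42, 500)
  expect_identical(running_median_baseline(x, 5, 200), rep(0, 500))
})

test_that("running median reproduces the hand-traced 5-point example", {
  # window of 3 samples; truncated centred windows all have median 0
  x <- c(0, 0, 10, 0, 0)
  w_min <- 3 * 200 / 60000  # 3 samples at 200 ms, in minutes
  expect_equal(running_median_baseline(x, w_min, 200), c(0, 0, 10, 0, 0))
})

test_that("running median is exactly invariant to adding any constant", {
  withr::with_seed(1, {
    # FLIC readings are integer a.u.; exactness holds whenever x + shift is
    # representable, which integer data guarantees
    x <- round(rnorm(400, 100, 5) + 30 * (runif(400) < 0.02))
    for (shift in c(-1000, 7, 1e6)) {
      expect_identical(running_median_baseline(x + shift, 2, 200),
                       running_median_baseline(x, 2, 200))
    }
  })
})

test_that("running median matches the direct truncated-window definition", {
  withr::with_seed(2, {
    x <- round(rnorm(777, 50, 10))
    k <- 31
    got <- running_median_baseline(x, k * 200 / 60000, 200)
    expect_equal(got, x - direct_running_median(x, k))
  })
})

test_that("ALS: constant and linear signals have (near-)zero residuals", {
  expect_lt(max(abs(als_baseline(rep(5, 100)))), 1e-6)
  ramp <- seq(0, 100, length.out = 200)
  res <- als_baseline(ramp)
  expect_lt(max(abs(res)), 1e-6 * diff(range(ramp)))
})

test_that("ALS iterative sparse solution matches the dense direct-solve oracle", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      y <- cumsum(rnorm(200)) + 50 * (runif(200) < 0.05)
      # smoothing timescale ~lambda^(1/4) samples must fit the instance
      lambda <- 10^runif(1, 3, 6)
      p <- runif(1, 0.005, 0.1)
      got <- als_baseline(y, lambda = lambda, p = p, max_iter = 20)
      z_oracle <- dense_als_estimate(y, lambda, p, max_iter = 20)
      expect_equal(got, y - z_oracle, tolerance = 1e-8)
    }
  })
})

test_that("ALS keeps the baseline under an isolated spike", {
  ramp <- seq(0, 50, length.out = 200)
  y <- ramp
  y[90:110] <- y[90:110] + 100  # rectangular spike of height 100
  res <- als_baseline(y)
  expect_equal(max(res[90:110]), 100, tolerance = 0.05 * 100)
  # matches the dense oracle (at a lambda whose smoothing timescale fits
  # the 200-sample instance)
  res6 <- als_baseline(y, lambda = 1e6)
  expect_equal(res6, y - dense_als_estimate(y, 1e6, 0.01), tolerance = 1e-8)
})

test_that("ALS residual is invariant (to 1e-6) under a constant shift", {
  withr::with_seed(4, {
    y <- cumsum(rnorm(300)) + 40 * (runif(300) < 0.03)
    r1 <- als_baseline(y)
    r2 <- als_baseline(y + 1000)
    expect_equal(r1, r2, tolerance = 1e-6)
  })
})

test_that("ALS fixed point does not depend on the initial weights", {
  # run the dense oracle from extreme starting weights; the package result
  # (which starts from uniform weights) must land on the same fixed point
  withr::with_seed(5, {
    for (rep in 1:5) {
      y <- cumsum(rnorm(120)) + 30 * (runif(120) < 0.05)
      got <- als_baseline(y, lambda = 1e5, p = 0.02, max_iter = 50)
      for (w0 in list(rep(0.02, 120), rep(0.98, 120))) {
        n <- 120
        mu <- mean(y)
        yc <- y - mu
        D <- diff(diag(n), differences = 2)
        C <- 1e5 * t(D) %*% D
        tie_eps <- 1e-6 * max(1, diff(range(yc)))
        w <- w0
        for (it in 1:50) {
          A <- C + diag(w)
          b <- w * yc
          z <- solve(A, b)
          z <- as.numeric(z + solve(A, b - A %*% z))
          w_new <- ifelse(yc - z > tie_eps, 0.02, 1 - 0.02)
          if (all(w_new == w)) break
          w <- w_new
        }
        expect_equal(got, yc - as.numeric(z), tolerance = 1e-7)
      }
    }
  })
})

test_that("baselining a table preserves shape, handles all wells, reports well errors", {
  sim <- small_simulation(seed = 6, n_wells = 3, days = 0.3)
  for (m in c("rm", "als")) {
    b <- baseline_table(sim$signals, method = m)
    expect_identical(dim(b), dim(sim$signals))
    expect_identical(b$time_ms, sim$signals$time_ms)
    expect_true(all(is.finite(c(b$W1, b$W2, b$W3))))
  }
  # all-constant table -> all-zero baselined table
  const <- sim$signals
  for (w in paste0("W", 1:3)) const[[w]] <- 7
  bc <- baseline_table(const, method = "rm")
  expect_true(all(bc$W1 == 0 & bc$W2 == 0 & bc$W3 == 0))

  bad <- sim$signals
  bad$W2[5] <- NA
  expect_error(baseline_table(bad, method = "rm"), "W2")
})

test_that("chunked processing leaves no seam artifacts", {
  # a smooth signal processed in 3 chunks must match the unchunked result
  # to well below 1e-6 of its range
  withr::with_seed(7, {
    n <- 3 * 3600  # 3 h at 1 Hz
    t <- seq_len(n)
    y <- 100 + 20 * sin(2 * pi * t / n) + rnorm(n, 0, 1)
    sim <- simulate_experiment(simulation_params(
      n_wells = 1, duration_days = n / 86400, n_ld_days = 0, n_dd_days = 1,
      sample_interval_ms = 1000, noise_sd = 0, drift_amplitude = 0,
      bout_rate_profile = rate_flat(0), seed = 1
    ))
    tab <- sim$signals
    tab$W1 <- y
    chunked <- baseline_table(tab, method = "rm", chunk_hours = 1)
    whole <- baseline_table(tab, method = "rm", chunk_hours = 1e6)
    expect_lt(max(abs(chunked$W1 - whole$W1)), 1e-6 * diff(range(y)))

    chunked_als <- baseline_table(tab, method = "als", chunk_hours = 1)
    whole_als <- baseline_table(tab, method = "als", chunk_hours = 1e6)
    expect_lt(max(abs(chunked_als$W1 - whole_als$W1)), 1e-6 * diff(range(y)))
  })
})

test_that("binned preview aggregates samples into the documented bins", {
  sim <- simulate_experiment(simulation_params(
    n_wells = 1, duration_days = 2 / 24, n_ld_days = 0, n_dd_days = 1,
    sample_interval_ms = 60000, noise_sd = 0, drift_amplitude = 0,
    bout_rate_profile = rate_flat(0), baseline_level = 0, seed = 1
  ))
  tab <- sim$signals
  tab$W1 <- seq_len(nrow(tab))  # 120 one-minute samples over 2 h
  pv <- binned_preview(tab, 60, "sum")
  expect_identical(nrow(pv), 2L)
  expect_equal(pv$value, c(sum(1:60), sum(61:120)))

  # mean of a constant is the constant
  tab$W1 <- rep(3, nrow(tab))
  pv2 <- binned_preview(tab, 60, "mean")
  expect_equal(pv2$value, c(3, 3))

  # 30 min of data with 1 h bins -> a single bin
  half <- tab[tab$time_ms < 30 * 60000, ]
  pv3 <- binned_preview(half, 60, "sum")
  expect_identical(nrow(pv3), 1L)
})
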