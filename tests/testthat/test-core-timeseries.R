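test_that("gap filling interpolates interior runs and holds edges", {
  s <- sampled_series(c(1, NA, 3), 10)
  expect_equal(fill_gaps_linear(s)$values, c(1, 2, 3))

  # no gaps: identity
  s2 <- sampled_series(c(4, 5, 6), 10)
  expect_equal(fill_gaps_linear(s2)$values, c(4, 5, 6))

  # long gap, endpoint-slope oracle v(n) = v0 + n * (v1 - v0) / (gap + 1)
  s3 <- sampled_series(c(0, rep(NA, 10), 22), 10)
  expect_equal(fill_gaps_linear(s3)$values, seq(0, 22, by = 2))

  # leading/trailing gaps hold the nearest valid value
  s4 <- sampled_series(c(NA, NA, 5, 7, NA), 10)
  expect_equal(fill_gaps_linear(s4)$values, c(5, 5, 5, 7, 7))

  # filled frames are recorded for downstream confidence checks
  expect_equal(attr(fill_gaps_linear(s4), "filled"),
               c(TRUE, TRUE, FALSE, FALSE, TRUE))

  expect_error(fill_gaps_linear(sampled_series(c(NA, NA), 10)),
               class = "nodsync_gap_fill_error")
})

test_that("gap filling is idempotent", {
  set.seed(7)
  for (i in 1:10) {
    v <- rnorm(100)
    v[sample(100, 20)] <- NA
    s <- sampled_series(v, 50)
    once <- fill_gaps_linear(s)
    twice <- fill_gaps_linear(once)
    expect_equal(twice$values, once$values)
  }
})

test_that("velocity of a constant series is zero and a ramp recovers its slope", {
  const <- sampled_series(rep(5, 400), 200)
  v <- differentiate_velocity(const)
  expect_lt(max(abs(v$values)), 1e-9)
  expect_equal(n_frames(v), 400)

  # ramp with slope 2 units/s at 200 Hz; interior = frames more than
  # 5 filter time constants (5 / (2 pi 10) s ~ 16 frames) from each edge
  t <- (0:399) / 200
  ramp <- sampled_series(2 * t, 200)
  vr <- differentiate_velocity(ramp)$values
  interior <- 60:340
  expect_lt(max(abs(vr[interior] - 2)), 0.02)

  expect_error(differentiate_velocity(sampled_series(c(1, NA, 3), 10)),
               class = "nodsync_precondition_error")
  expect_error(differentiate_velocity(sampled_series(1:4, 200)),
               class = "nodsync_filter_error")
  expect_error(
    differentiate_velocity(sampled_series(1:100, 10),
                           filter_params(cutoff_hz = 10)),
    class = "nodsync_filter_error")
})

test_that("sinusoid velocity amplitude matches the analytic derivative times the filter gain", {
  f <- 1; A <- 10; fs <- 100
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  s <- sampled_series(A * sin(2 * pi * f * t), fs)
  fp <- filter_params(order = 2, cutoff_hz = 10)
  v <- differentiate_velocity(s, fp)$values

  # oracle: |H(f)|^2 of the Butterworth (applied forward + backward), times
  # the central-difference gain sin(w dt)/(w dt), times the true amplitude
  bw <- signal::butter(fp$order, fp$cutoff_hz / (fs / 2), type = "low")
  z <- exp(1i * 2 * pi * f / fs)
  H <- sum(bw$b * z^(-(seq_along(bw$b) - 1))) /
    sum(bw$a * z^(-(seq_along(bw$a) - 1)))
  wdt <- 2 * pi * f / fs
  expected <- 2 * pi * f * A * Mod(H)^2 * sin(wdt) / wdt

  interior <- 150:850
  expect_equal(max(abs(v[interior])), expected, tolerance = 0.01)
})

test_that("differentiation is linear", {
  set.seed(11)
  x <- sampled_series(rnorm(300), 100)
  y <- sampled_series(rnorm(300), 100)
  a <- 2.5; b <- -1.3
  comb <- sampled_series(a * x$values + b * y$values, 100)
  lhs <- differentiate_velocity(comb)$values
  rhs <- a * differentiate_velocity(x)$values +
    b * differentiate_velocity(y)$values
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("zero-phase filtering keeps the dip's velocity zero-crossing at the position minimum", {
  for (apex in c(2.0, 3.7, 5.55)) {
    s <- dip_series(rate_hz = 200, apex_s = apex)
    v <- differentiate_velocity(s)$values
    pos_min <- which.min(s$values) - 1L         # 0-based
    cross <- oracle_sync_frame(v, threshold = min(v) / 2)
    expect_lte(abs(cross - pos_min), 1)
  }
})

test_that("prefix zeroing blanks exactly floor(duration * rate) frames", {
  s <- sampled_series(rep(1, 600), 120)
  z <- zero_prefix(s, 1.5)
  expect_equal(z$values[1:180], rep(0, 180))
  expect_equal(z$values[181:600], rep(1, 420))

  expect_equal(zero_prefix(s, 0)$values, s$values)

  s50 <- sampled_series(rep(1, 200), 50)
  expect_equal(sum(zero_prefix(s50, 1.0)$values == 0), 50)

  expect_error(zero_prefix(s50, 10), class = "nodsync_prefix_error")
})

test_that("z-scoring standardizes, rejects constants, and is idempotent", {
  set.seed(3)
  s <- sampled_series(rnorm(500, 20, 4), 100)
  z <- zscore_series(s)
  expect_lt(abs(mean(z$values)), 1e-9)
  expect_lt(abs(sd(z$values) - 1), 1e-9)
  expect_equal(zscore_series(z)$values, z$values, tolerance = 1e-12)

  # sd convention: sample (n-1), pinned because the threshold is in z-units
  s2 <- sampled_series(c(0, 0, 0, -4), 10)
  expect_equal(zscore_series(s2)$values, c(0.5, 0.5, 0.5, -1.5))
  expect_equal(zscore_series(s2, sd_type = "population")$values,
               (c(0, 0, 0, -4) + 1) / sqrt(3))

  expect_error(zscore_series(sampled_series(c(3, 3, 3), 10)),
               class = "nodsync_degenerate_series_error")
})
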