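make_flank <- function(n = 200) {
  # descending flank reaching -3 at frame 105 (0-based), ascending flank
  # with v[110] = -0.3, v[111] = +0.3, zero elsewhere
  v <- rep(0, n)
  v[101:106] <- -c(0.5, 1, 1.5, 2, 2.5, 3)   # frames 100..105
  v[107:111] <- -c(2.5, 1.8, 1.2, 0.6, 0.3)  # frames 106..110
  v[112] <- 0.3                              # frame 111
  v
}

test_that("forward detection returns the frame before the zero-crossing after the first sub-threshold minimum", {
  v <- make_flank()
  sp <- detect_sync_point(sampled_series(v, 100), -2, "forward", "mocap")
  expect_equal(sp$frame, 110L)
  expect_equal(sp$time_s, 110 / 100)
  expect_equal(sp$method, "velocity")
  expect_false(sp$low_confidence)
  # agrees with the exhaustive-scan oracle
  expect_equal(sp$frame, oracle_sync_frame(v, -2))
})

test_that("detection fails cleanly when no minimum beats the threshold or no crossing follows", {
  expect_error(detect_sync_point(sampled_series(rep(0, 50), 100), -2),
               class = "nodsync_no_nod_error")
  # dips but never below -2
  shallow <- sampled_series(c(rep(0, 10), -1, rep(0, 10)), 100)
  expect_error(detect_sync_point(shallow, -2),
               class = "nodsync_no_nod_error")
  # sub-threshold minimum but velocity stays negative to the end
  stuck <- sampled_series(c(rep(0, 5), -3, rep(-0.5, 5)), 100)
  expect_error(detect_sync_point(stuck, -2),
               class = "nodsync_no_zero_crossing_error")
})

test_that("reverse detection finds the last sub-threshold minimum and its forward crossing", {
  v <- make_flank(400)
  # add a second, later nod: same shape shifted by 200 frames
  v[301:312] <- v[101:112]
  s <- sampled_series(v, 100)
  expect_equal(detect_sync_point(s, -2, "forward")$frame, 110L)
  expect_equal(detect_sync_point(s, -2, "reverse")$frame, 310L)
  expect_equal(detect_sync_point(s, -2, "reverse")$frame,
               oracle_sync_frame(v, -2, reverse = TRUE))

  # time-mirrored single flank near the stream end, checked against the
  # oracle applied to the mirrored array
  vm <- rev(make_flank())
  sm <- sampled_series(vm, 100)
  expect_equal(detect_sync_point(sm, -2, "reverse")$frame,
               oracle_sync_frame(vm, -2, reverse = TRUE))
})

test_that("plateau minima resolve to their first frame", {
  v <- rep(0, 30)
  v[11:14] <- c(-1, -3, -3, -1)   # plateau of -3 at frames 11-12 (1-based)
  v[15] <- 0.2
  sp <- detect_sync_point(sampled_series(v, 10), -2)
  # crossing: v[14] = -1 < 0, v[15] = 0.2 >= 0 -> frame 13 (0-based)
  expect_equal(sp$frame, 13L)
  expect_equal(sp$frame, oracle_sync_frame(v, -2))
})

test_that("position-minimum ground truth picks the global minimum, first frame on ties", {
  expect_equal(ground_truth_minimum(sampled_series(c(3, 1, 2), 10))$frame, 1L)
  expect_equal(ground_truth_minimum(sampled_series(c(3, 1, 1, 3), 10))$frame,
               1L)
  # window restriction
  s <- sampled_series(c(0, -5, 0, 0, -1, 0), 1)
  expect_equal(ground_truth_minimum(s, window = c(3, 5))$frame, 4L)
  expect_error(ground_truth_minimum(s, window = c(10, 11)),
               class = "nodsync_precondition_error")
  expect_error(ground_truth_minimum(sampled_series(c(1, NA, 3), 10)),
               class = "nodsync_precondition_error")

  # noise-free simulated session: ground truth equals the simulator apex
  ses <- clean_session(seed = 1, noise = FALSE)
  pos <- fill_gaps_linear(marker_channel(ses$mocap, "head_front_left"))
  gt <- ground_truth_minimum(pos)
  expect_lte(abs(gt$frame - ses$truth$apex_frame_mocap), 1)
})

test_that("prepare_channel yields a standardized velocity with the nod as unique sub-threshold minimum", {
  ses <- clean_session(seed = 1)
  vz <- prepare_channel(marker_channel(ses$mocap, "head_front_left"),
                        nod_params(), prefix_s = 1.5)
  expect_lt(abs(mean(vz$values)), 1e-9)
  expect_lt(abs(sd(vz$values) - 1), 1e-9)
  expect_lt(min(vz$values), -2)
  # the global minimum sits on the nod's descending flank
  expect_lt(abs((which.min(vz$values) - 1) / 200 - 3.4), 0.2)

  # constant trace cannot be standardized
  const <- sampled_series(rep(3, 1000), 200)
  expect_error(prepare_channel(const, nod_params(), 1.5),
               class = "nodsync_degenerate_series_error")

  # a dip destroyed by the zeroed prefix leaves nothing real to detect:
  # the outcome is a clean failure or a low-confidence flag, never a
  # confident sync point
  early <- simulate_session(sim_config(seed = 2, true_offset_s = 0.1,
                                       nod_time_s = 1.0))
  vz_early <- prepare_channel(marker_channel(early$mocap, "head_front_left"),
                              nod_params(), prefix_s = 1.5)
  res <- tryCatch(detect_sync_point(vz_early, -2),
                  nodsync_error = function(e) e)
  expect_true(inherits(res, "nodsync_no_nod_error") ||
                isTRUE(res$low_confidence))

  # dip_sign flips an inverted channel into a detectable minimum
  flipped <- marker_channel(ses$mocap, "head_front_left")
  flipped <- sampled_series(-flipped$values, flipped$rate_hz)
  vz_flip <- prepare_channel(flipped, nod_params(dip_sign = -1), 1.5)
  expect_equal(detect_sync_point(vz_flip, -2)$frame,
               detect_sync_point(vz, -2)$frame)
})

test_that("velocity sync point agrees with the position-minimum oracle on clean sessions", {
  for (seed in 1:5) {
    ses <- clean_session(seed = seed, offset = 0.7 + 0.2 * seed,
                         noise = FALSE)
    fit <- sync_nod(ses$mocap, ses$gaze)
    gt_m <- ground_truth_minimum(
      fill_gaps_linear(marker_channel(ses$mocap, "head_front_left")))
    gt_e <- ground_truth_minimum(fill_gaps_linear(ses$gaze$pupil_y))
    expect_lte(abs(fit$sp_mocap$frame - gt_m$frame), 1)
    expect_lte(abs(fit$sp_eye$frame - gt_e$frame), 1)
  }
})

test_that("relaxing the threshold never moves the start-nod sync point later", {
  for (seed in c(3, 9, 21)) {
    ses <- clean_session(seed = seed)
    vz <- prepare_channel(marker_channel(ses$mocap, "head_front_left"),
                          nod_params(), 1.5)
    frames <- vapply(c(-4, -3, -2, -1), function(th)
      detect_sync_point(vz, th)$frame, integer(1))
    expect_true(all(diff(frames) <= 0))
  }
})

test_that("shifting the velocity input shifts the sync point by the same amount", {
  v <- make_flank()
  base <- detect_sync_point(sampled_series(v, 100), -2)$frame
  for (k in c(5, 17, 40)) {
    shifted <- c(rep(0, k), v)
    sp <- detect_sync_point(sampled_series(shifted, 100), -2)
    expect_equal(sp$frame, base + k)
  }
})

test_that("forward and reverse detection coincide on single-nod sessions", {
  for (seed in 4:6) {
    ses <- clean_session(seed = seed)
    fwd <- sync_nod(ses$mocap, ses$gaze, direction = "forward")
    rev <- sync_nod(ses$mocap, ses$gaze, direction = "reverse")
    expect_equal(fwd$sp_mocap$frame, rev$sp_mocap$frame)
    expect_equal(fwd$sp_eye$frame, rev$sp_eye$frame)
  }
})

test_that("a blink overlapping the nod flanks flags the sync point low-confidence", {
  ses <- clean_session(seed = 1, noise = FALSE)
  # nod apex at world 3.5 s = eye-clock 2.5 s; flanks span ~2.3-2.7 s.
  # blink over the descending flank only: detection still succeeds but is
  # mostly interpolated
  blinked <- inject_blink(ses$gaze, 2.28, 0.20)
  vz <- prepare_channel(blinked$pupil_y, nod_params(), 1.0)
  sp <- detect_sync_point(vz, -2, "forward", "eye")
  expect_true(sp$low_confidence)
})
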