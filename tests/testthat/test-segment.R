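test_that("the resolution threshold reproduces the published value", {
  expect_equal(threshold_nm_per_min(72.2, 10, 5), 86.64)
  expect_lt(abs(threshold_nm_per_min(72.2, 10, 5) - 86.7), 0.1)
  expect_equal(threshold_nm_per_min(72.2, 1, 60), 72.2)
  expect_equal(threshold_nm_per_min(100, 10, 6), 100)
  expect_error(threshold_nm_per_min(-1, 10, 5))
})

test_that("a constant-velocity lateral track is one run at its velocity", {
  pos <- piecewise_positions(0.56, 1800)
  tr <- new_track("cv", pos, frame_interval = 5)
  seg <- segment_track(tr)
  expect_equal(nrow(seg$segments), 1)
  expect_equal(seg$segments$state, "run_plus")
  expect_equal(seg$segments$velocity, 0.56, tolerance = 1e-6)
  expect_true(is.na(seg$end_on_frame))
})

test_that("a stationary track is one pause with zero moving time", {
  tr <- new_track("still", rep(1.4, 200), frame_interval = 5)
  seg <- segment_track(tr)
  expect_equal(seg$segments$state, "paused")
  s <- summarize_track(seg, tr)
  expect_equal(s$lateral_moving_fraction, 0)
  expect_false(s$moved_at_all)
})

test_that("a slope exactly at threshold counts as moving", {
  # 72.2 nm per 50 s, the boundary case of the published rule
  v_thr <- 72.2e-3 / 50 * 60                      # um/min
  pos <- piecewise_positions(v_thr, 1800)
  seg <- segment_track(new_track("thr", pos, frame_interval = 5))
  expect_equal(seg$segments$state, "run_plus")
  # and one just below is paused
  seg2 <- segment_track(new_track("sub", piecewise_positions(v_thr * 0.98,
                                                             1800),
                                  frame_interval = 5))
  expect_equal(seg2$segments$state, "paused")
})

test_that("a run-pause-run track segments into three parts with hand-computed stats", {
  # 2 min at 0.6, 3 min at 0, 2 min at 0.5 um/min
  pos <- piecewise_positions(c(0.6, 0, 0.5), c(120, 180, 120))
  tr <- new_track("pw", pos, frame_interval = 5)
  seg <- segment_track(tr)
  s <- seg$segments
  expect_equal(s$state, c("run_plus", "paused", "run_plus"))
  # boundaries recovered within one window of the true junctions (frames 24, 60)
  expect_lt(abs(s$end_frame[1] - 23), 10)
  expect_lt(abs(s$end_frame[2] - 59), 10)
  expect_equal(s$displacement_um[1], 1.2, tolerance = 0.12)
  expect_equal(s$displacement_um[3], 1.0, tolerance = 0.12)
  expect_equal(s$velocity[1], 0.6, tolerance = 0.02)
  expect_equal(s$velocity[3], 0.5, tolerance = 0.02)
  ms <- summarize_track(seg, tr)
  expect_equal(ms$n_runs, 2)
  expect_equal(ms$lateral_moving_fraction, 4 / 7, tolerance = 0.08)
})

test_that("movements shorter than one window fold into the surrounding pause", {
  # an 8 s (sub-window, sub-threshold-span) twitch inside a long pause
  pos <- piecewise_positions(c(0, 1.0, 0), c(300, 8, 292))
  seg <- segment_track(new_track("twitch", pos, frame_interval = 5))
  expect_false("run_plus" %in% seg$segments$state)
})

test_that("the lateral to end-on transition is detected and tip phases labeled", {
  # approach at 0.56 um/min to a 2.05 um tip (reached near frame 33), then
  # track depolymerization at 0.4 um/min
  n1 <- 34
  n2 <- 200
  kt <- c(pmin(0.5 + 0.56 / 60 * 5 * (0:(n1 - 1)), 2.05),
          2.05 - 0.4 / 60 * 5 * (1:n2))
  mt <- c(rep(2.05, n1), 2.05 - 0.4 / 60 * 5 * (1:n2))
  tr <- new_track("conv", kt, frame_interval = 5)
  seg <- segment_track(tr, mt)
  expect_false(is.na(seg$end_on_frame))
  expect_lt(abs(seg$end_on_frame - 32), 12)
  tips <- seg$segments[seg$segments$state %in% c("tip_track", "tip_paused"), ]
  expect_gt(nrow(tips), 0)
  tt <- tips[tips$state == "tip_track", ]
  expect_equal(stats::weighted.mean(tt$velocity,
                                    tt$end_frame - tt$start_frame + 1),
               -0.4, tolerance = 0.02)
  # no run_plus after the transition
  after <- seg$segments$start_frame >= seg$end_on_frame
  expect_false(any(seg$segments$state[after] == "run_plus"))
})

test_that("segments tile the track exactly", {
  set.seed(17)
  p <- make_preset("WT")
  for (i in 1:5) {
    mt <- simulate_microtubule(p, 1800, 5)
    kt <- simulate_kinetochore(p, mt)
    tr <- track_from_trajectory(kt)
    seg <- segment_track(tr, kt$mt_plus_end)
    s <- seg$segments
    expect_equal(s$start_frame[1], 0L)
    expect_equal(s$end_frame[nrow(s)], 359L)
    if (nrow(s) > 1)
      expect_true(all(s$start_frame[-1] == s$end_frame[-nrow(s)] + 1L))
  }
})

test_that("raising the pause threshold never increases the moving fraction", {
  set.seed(19)
  p <- make_preset("WT")
  thresholds <- c(40, 86.64, 150, 300, 500)
  for (i in 1:4) {
    mt <- simulate_microtubule(p, 1800, 5)
    kt <- simulate_kinetochore(p, mt)
    tr <- track_from_trajectory(kt)
    # strict monotonicity for the pure threshold-label estimator
    fr0 <- vapply(thresholds, function(thr) {
      seg <- segment_track(tr, kt$mt_plus_end, threshold = thr,
                           refine = FALSE)
      summarize_track(seg, tr)$lateral_moving_fraction
    }, numeric(1))
    expect_true(all(diff(fr0) <= 1e-12))
    # with boundary refinement, monotone up to the per-junction jitter of
    # the changepoint search (bounded by one window of frames)
    res <- lapply(thresholds, function(thr)
      segment_track(tr, kt$mt_plus_end, threshold = thr))
    fr1 <- vapply(res, function(sg)
      summarize_track(sg, tr)$lateral_moving_fraction, numeric(1))
    n_lat <- summarize_track(res[[1]], tr)$lateral_frames
    jitter <- 10 / max(n_lat, 1)
    expect_true(all(diff(fr1) <= jitter + 1e-12))
  }
})

test_that("degenerate and flagged inputs are rejected", {
  tr <- new_track("short", rep(1, 8), frame_interval = 5)
  expect_error(segment_track(tr), "shorter than the slope window")
  tr2 <- new_track("ok", rep(1, 50), frame_interval = 5)
  expect_error(segment_track(tr2, window_frames = 1), "window_frames")
  expect_error(segment_track(tr2, qc_crossed = TRUE), "crossed or bundled")
  expect_error(segment_track(tr2, mt_end = rep(2, 10)), "length")
})
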