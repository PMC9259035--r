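test_that("per-track summaries report the hand-computed run statistics", {
  pos <- piecewise_positions(c(0.6, 0, 0.5), c(120, 180, 120))
  tr <- new_track("pw", pos, frame_interval = 5)
  s <- summarize_track(segment_track(tr), tr)
  expect_equal(s$n_runs, 2)
  expect_equal(sort(s$run_lengths), c(1.0, 1.2), tolerance = 0.12)
  expect_true(s$moved_at_all)
  expect_false(s$reached_plus_end)
  expect_equal(s$lateral_moving_fraction + (1 - s$lateral_moving_fraction), 1)
})

test_that("an all-paused track has no velocity and is excluded from cohort velocity means", {
  still <- new_track("still", rep(2, 150), frame_interval = 5)
  s_still <- summarize_track(segment_track(still), still)
  expect_true(is.na(s_still$mean_run_velocity))
  expect_false(s_still$moved_at_all)

  mover <- new_track("mv", piecewise_positions(0.5, 750), frame_interval = 5)
  s_mv <- summarize_track(segment_track(mover), mover)
  cs <- summarize_cohort(list(s_still, s_mv))
  expect_equal(cs$run_velocity_mean, s_mv$mean_run_velocity)
  expect_equal(cs$fraction_moved, 0.5)           # still counted in denominator
})

test_that("a pure tip-tracking phase gives tip speed 0.4 and tip moving fraction 1", {
  n1 <- 30
  kt <- c(pmin(1 + 0.56 / 60 * 5 * (0:(n1 - 1)), 2.2),
          2.2 - 0.4 / 60 * 5 * (1:150))
  mt <- c(rep(2.2, n1), 2.2 - 0.4 / 60 * 5 * (1:150))
  tr <- new_track("tip", kt, frame_interval = 5)
  s <- summarize_track(segment_track(tr, mt), tr)
  expect_true(s$reached_plus_end)
  expect_equal(s$mean_tip_velocity, 0.4, tolerance = 0.02)
  expect_equal(s$tip_moving_fraction, 1, tolerance = 0.1)
})

test_that("cohort means and SEMs follow the textbook formulas", {
  mk <- function(v) structure(list(trajectory_id = "x",
    mean_run_velocity = v, gross_lateral_velocity = v,
    mean_tip_velocity = NA_real_, run_lengths = v, n_runs = 1L,
    lateral_frames = 100L, lateral_moving_fraction = 0.5,
    tip_frames = 0L, tip_moving_fraction = NA_real_,
    lateral_moving_frames = 50L, tip_moving_frames = 0L,
    moved_at_all = TRUE, reached_plus_end = FALSE),
    class = "motility_summary")
  cs <- summarize_cohort(list(mk(0.5), mk(0.7)))
  expect_equal(cs$run_velocity_mean, 0.6)
  expect_equal(cs$run_velocity_sem, 0.1)          # sd/sqrt(2)
  single <- summarize_cohort(list(mk(0.5)))
  expect_equal(single$run_velocity_sem, 0)        # n = 1 convention
  expect_true(single$fraction_moved %in% c(0, 1))
  expect_error(summarize_cohort(list()), "empty")
})

test_that("tip statistics stop once the microtubule is fully depolymerized", {
  # depolymerize to the seed halfway through, then sit at 0
  n1 <- 20
  down <- 2 - 0.8 / 60 * 5 * (1:150)
  kt <- c(pmin(1.2 + 0.56 / 60 * 5 * (0:(n1 - 1)), 2), pmax(down, 0))
  mt <- kt; mt[seq_len(n1)] <- 2
  tr <- new_track("seed", kt, frame_interval = 5)
  s <- summarize_track(segment_track(tr, mt), tr)
  # frames clamped at the seed are excluded from the tip-phase denominator
  expect_lt(s$tip_frames, 150)
  expect_gt(s$tip_moving_fraction, 0.5)
})
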