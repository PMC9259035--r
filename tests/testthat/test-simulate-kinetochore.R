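wt <- make_preset("WT")

# a preset whose microtubule can never reach or be reached by the kinetochore,
# so the lateral phase lasts the whole movie
lateral_only <- function(base = wt) {
  p <- base
  p$f_cat <- 0; p$v_growth <- 5; p$L0_range <- c(20, 20)
  p$x0_fraction_range <- c(0.05, 0.1)
  p
}

test_that("non-motile kinetochores hold position while lateral", {
  p <- lateral_only()
  p$p_motile <- 0
  mt <- simulate_microtubule(p, 1800, 5, seed = 3)
  kt <- simulate_kinetochore(p, mt, seed = 4)
  expect_false(kt$motile)
  lat <- kt$attachment == "lateral"
  expect_equal(stats::sd(kt$kt_position[lat]), 0)
  expect_true(all(kt$state[lat] == "lateral_pause"))
})

test_that("with vanishing pauses the track is one uninterrupted run at v_run", {
  p <- lateral_only()
  p$p_motile <- 1; p$t_pause_mean <- 1e-9
  mt <- simulate_microtubule(p, 600, 5, seed = 5)
  kt <- simulate_kinetochore(p, mt, seed = 6)
  lat <- which(kt$attachment == "lateral")
  gross <- (kt$kt_position[max(lat)] - kt$kt_position[min(lat)]) /
    ((max(lat) - min(lat)) * 5 / 60)
  expect_equal(gross, p$v_run, tolerance = 1e-6)
})

test_that("lateral state occupancy matches the two-state closed form", {
  p <- lateral_only()
  p$p_motile <- 1
  expected <- p$t_run_mean / (p$t_run_mean + p$t_pause_mean)
  set.seed(11)
  fr <- vapply(1:40, function(i) {
    mt <- simulate_microtubule(p, 1800, 5)
    kt <- simulate_kinetochore(p, mt)
    mean(kt$state[kt$attachment == "lateral"] == "lateral_run")
  }, numeric(1))
  # 40 x 360 frames > 10,000 lateral frames pooled
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - expected), 3 * se)
})

test_that("trajectory invariants hold across a cohort", {
  ts <- simulate_cohort(wt, n = 30, duration = 1800, frame_interval = 5,
                        seed = 8)
  tol <- 72.2 / 1000
  for (kt in ts$trajectories) {
    expect_true(all(kt$kt_position <= kt$mt_plus_end + tol))
    sw <- rle(kt$attachment)
    expect_lte(length(sw$values), 2)                 # lateral -> end_on once
    if (length(sw$values) == 2)
      expect_equal(sw$values, c("lateral", "end_on"))
    eo <- which(kt$attachment == "end_on")
    if (length(eo) > 1) {
      expect_true(all(diff(kt$mt_plus_end[eo]) <= 1e-9))  # no regrowth
      expect_equal(kt$kt_position[eo], kt$mt_plus_end[eo])
      # tip-coupled shrinkage never exceeds the tip-tracking velocity
      expect_true(all(diff(kt$kt_position[eo]) >=
                        -wt$v_tip_track / 60 * 5 - 1e-9))
    }
    expect_true(all(is.finite(kt$kt_position)))      # never detaches
  }
})

test_that("longer pauses strictly slow the gross lateral speed", {
  base <- lateral_only()
  base$p_motile <- 1
  gross_speed <- function(t_pause, seed) {
    p <- base; p$t_pause_mean <- t_pause
    mt <- simulate_microtubule(p, 1800, 5, seed = seed)
    kt <- simulate_kinetochore(p, mt, seed = seed + 1000)
    lat <- which(kt$attachment == "lateral")
    (kt$kt_position[max(lat)] - kt$kt_position[min(lat)]) /
      ((max(lat) - min(lat)) * 5 / 60)
  }
  speeds <- vapply(c(10, 60, 200), function(tp)
    mean(vapply(1:12, function(s) gross_speed(tp, s), numeric(1))),
    numeric(1))
  expect_true(all(diff(speeds) < 0))
})

test_that("cohorts are reproducible under a seed and distinct across seeds", {
  a <- simulate_cohort(wt, 4, 600, 5, seed = 21)
  b <- simulate_cohort(wt, 4, 600, 5, seed = 21)
  expect_identical(lapply(a$trajectories, `[[`, "kt_position"),
                   lapply(b$trajectories, `[[`, "kt_position"))
  d <- simulate_cohort(wt, 4, 600, 5, seed = 22)
  expect_false(identical(a$trajectories[[1]]$kt_position,
                         d$trajectories[[1]]$kt_position))
  expect_error(simulate_cohort(wt, 0, 600, 5), "positive")
})

test_that("cohort geometry matches the movie parameters", {
  ts <- simulate_cohort(wt, n = 3, duration = 1800, frame_interval = 5,
                        seed = 31)
  expect_length(ts$trajectories, 3)
  for (kt in ts$trajectories) expect_length(kt$times, 360)
})

test_that("trajectory sets round-trip through CSV", {
  ts <- simulate_cohort(wt, 3, 300, 5, seed = 41)
  path <- tempfile(fileext = ".csv")
  write_trajectories(ts, path)
  back <- read_trajectories(path)
  expect_length(back$trajectories, 3)
  for (i in 1:3) {
    expect_equal(back$trajectories[[i]]$kt_position,
                 ts$trajectories[[i]]$kt_position, tolerance = 1e-12)
    expect_identical(back$trajectories[[i]]$state, ts$trajectories[[i]]$state)
  }
  expect_equal(back$frame_interval, 5)
})
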