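test_that("a static noiseless emitter renders identical, centred columns", {
  kt <- manual_trajectory(rep(2.0, 60), mt_end = rep(4.0, 60))
  cfg <- imaging_config(duration = 300, noise_model = "none",
                        blink_off_mean = 0)
  ky <- render_kymograph(kt, cfg)
  img <- ky$data[2, , ]
  expect_true(all(img == img[, 1]))               # every column identical
  px <- cfg$pixel_size / 1000
  v <- img[, 1] - cfg$background
  centroid <- sum((seq_along(v) - 0.5) * v) / sum(v) * px
  expect_equal(centroid, 2.0, tolerance = 0.01)
  # microtubule channel covers seed..tip and nothing beyond
  mtc <- ky$data[1, , 1] - cfg$background
  expect_gt(mtc[10], 0)
  expect_lt(mtc[length(mtc)], 0.01)   # far PSF tail, well below one photon
})

test_that("kinetochore-channel energy is conserved without noise", {
  kt <- manual_trajectory(seq(1, 3, length.out = 120),
                          mt_end = rep(5, 120))
  cfg <- imaging_config(duration = 600, noise_model = "none",
                        blink_off_mean = 0)
  ky <- render_kymograph(kt, cfg)
  mass <- colSums(ky$data[2, , ] - cfg$background)
  expect_equal(mass, rep(cfg$photon_rate, 120), tolerance = 1e-6)
})

test_that("disabling blinking keeps the emitter visible in every frame", {
  kt <- manual_trajectory(rep(1.5, 80), mt_end = rep(3, 80))
  cfg <- imaging_config(duration = 400, blink_off_mean = 0,
                        blink_channel = "kinetochore")
  ky <- render_kymograph(kt, cfg, seed = 1)
  expect_true(all(ky$blink_visible["kinetochore", ]))
})

test_that("blinking duty cycle converges to on/(on+off)", {
  n <- 1440                                        # 2 h of frames
  kt <- manual_trajectory(rep(1.5, n), mt_end = rep(3, n))
  cfg <- imaging_config(duration = n * 5, blink_on_mean = 20,
                        blink_off_mean = 10)
  set.seed(5)
  duty <- vapply(1:12, function(i) {
    ky <- render_kymograph(kt, cfg)
    mean(ky$blink_visible["microtubule", ])
  }, numeric(1))
  se <- stats::sd(duty) / sqrt(length(duty))
  expect_lt(abs(mean(duty) - 20 / 30), 3 * se)
})

test_that("rendering is reproducible under a seed", {
  kt <- manual_trajectory(seq(1, 2, length.out = 40), mt_end = rep(4, 40))
  cfg <- imaging_config(duration = 200)
  a <- render_kymograph(kt, cfg, seed = 9)
  b <- render_kymograph(kt, cfg, seed = 9)
  expect_identical(a$data, b$data)
})

test_that("grid mismatch between trajectory and config is an error", {
  kt <- manual_trajectory(rep(1, 50))
  expect_error(render_kymograph(kt, imaging_config(duration = 300)),
               "grid")
})

test_that("per-frame centroid error stays below half a pixel under noise", {
  pos <- piecewise_positions(0.56, 1800, x0 = 1)
  kt <- manual_trajectory(pos, mt_end = rep(max(pos) + 1, length(pos)))
  cfg <- imaging_config()
  set.seed(7)
  rmse <- vapply(1:15, function(i) {
    ky <- render_kymograph(kt, cfg)
    tr <- extract_track(ky)
    sqrt(mean((tr$positions - pos)^2))
  }, numeric(1))
  expect_lt(mean(rmse), 0.5 * cfg$pixel_size / 1000)
})

test_that("kymographs round-trip through TIFF with calibration metadata", {
  kt <- manual_trajectory(seq(0.5, 2.5, length.out = 60),
                          mt_end = rep(4, 60))
  cfg <- imaging_config(duration = 300)
  ky <- render_kymograph(kt, cfg, seed = 3)
  path <- tempfile(fileext = ".tif")
  write_kymograph_tiff(ky, path)
  back <- read_kymograph_tiff(path)
  expect_equal(back$channels, ky$channels)
  expect_equal(back$calibration$pixel_size, 72.2)
  expect_equal(back$calibration$frame_interval, 5)
  expect_equal(back$data, ky$data, tolerance = 1e-6)
  # analysis on the re-read image gives the same track
  t1 <- extract_track(ky); t2 <- extract_track(back)
  expect_equal(t1$positions, t2$positions, tolerance = 1e-4)
})

test_that("spindle profiles have the declared geometry", {
  cfg <- imaging_config(noise_model = "none")
  bi <- render_spindle_profile("bilobed", 2.5, cfg, seed = 1)
  expect_s3_class(bi, "data.frame")
  y <- bi$intensity - min(bi$intensity)
  above <- y > max(y) / 2
  expect_equal(sum(diff(above) == 1), 2)          # two half-max excursions
  pl <- NULL
  for (s in 1:20) {                               # find a plateau variant
    d <- render_spindle_profile("declustered", 2.5, cfg, seed = s)
    if (sum(diff((d$intensity - min(d$intensity)) >
                   max(d$intensity - min(d$intensity)) / 2) == 1) == 1) {
      pl <- d; break
    }
  }
  expect_false(is.null(pl))
  expect_error(render_spindle_profile("bilobed", 3.5, cfg), "window")
})
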