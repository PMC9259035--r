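test_that("packaged presets carry the measured condition values", {
  wt <- make_preset("WT")
  expect_s3_class(wt, "genotype_preset")
  expect_equal(wt$v_run, 0.56)
  expect_equal(wt$p_motile, 0.77)
  expect_equal(wt$v_tip_track, 0.40)
  expect_equal(wt$v_depol_free, 0.82)

  k3 <- make_preset("kip3_null")
  expect_equal(k3$v_run, 0.47)
  expect_equal(k3$p_motile, 0.28)
  expect_lt(k3$t_run_mean, wt$t_run_mean)      # shorter runs without the motor
  expect_lt(k3$f_cat, wt$f_cat)                # fewer catastrophes

  dtlz <- make_preset("kip3_dT_LZ")
  expect_equal(dtlz$v_run, 0.76)
  expect_lt(dtlz$f_cat, wt$f_cat)

  expect_equal(make_preset("mif2_like")$v_run, 0.56 * 0.71)
})

test_that("preset dwell ratio defines the motile occupancy and x0 range is valid", {
  for (g in c("WT", "kip3_null", "kip3_dT_LZ")) {
    p <- make_preset(g)
    occ <- p$t_run_mean / (p$t_run_mean + p$t_pause_mean)
    expect_gt(occ, 0); expect_lt(occ, 1)
    expect_true(p$x0_fraction_range[1] >= 0 && p$x0_fraction_range[2] < 1)
    expect_true(all(c(p$v_run, p$v_tip_track, p$v_growth) > 0))
  }
})

test_that("unknown presets fail loudly and name the available ones", {
  expect_error(make_preset("nope"), "unknown genotype preset 'nope'")
  expect_error(make_preset("nope"), "WT")
})

test_that("config overrides extend and modify presets", {
  cfg <- list(WT = list(v_run = 1.0),
              custom = list(v_run = 0.3, t_run_mean = 40, t_pause_mean = 60,
                            p_motile = 0.5, v_tip_track = 0.2,
                            t_tipmove_mean = 50, t_tippause_mean = 50,
                            v_growth = 0.5, f_cat = 0.2, f_res = 1,
                            v_depol_free = 0.8, L0_range = c(2, 4),
                            x0_fraction_range = c(0.2, 0.8)))
  expect_equal(make_preset("WT", cfg)$v_run, 1.0)
  expect_equal(make_preset("WT", cfg)$p_motile, 0.77)   # untouched fields kept
  expect_equal(make_preset("custom", cfg)$v_run, 0.3)
})

test_that("invalid presets are rejected", {
  bad <- list(WT = list(p_motile = 1.5))
  expect_error(make_preset("WT", bad), "p_motile")
  expect_error(make_preset("WT", list(WT = list(v_run = -1))), "v_run")
})

test_that("presets round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  presets <- list(WT = make_preset("WT"), kip3_null = make_preset("kip3_null"))
  write_preset_config(presets, path)
  cfg <- read_preset_config(path)
  back <- make_preset("WT", cfg)
  for (f in setdiff(names(unclass(presets$WT)), "name"))
    expect_equal(back[[f]], presets$WT[[f]], info = f)
})

test_that("the packaged presets.yaml matches the built-in defaults", {
  path <- system.file("config", "presets.yaml", package = "kinetotrack")
  expect_true(nzchar(path))
  cfg <- read_preset_config(path)
  expect_setequal(names(cfg),
                  c("WT", "kip3_null", "kip3_dT_LZ", "mif2_like"))
  expect_equal(cfg$WT$v_run, make_preset("WT")$v_run)
  expect_equal(cfg$kip3_null$f_cat, make_preset("kip3_null")$f_cat)
})
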