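test_that("spectral library is deterministic, non-negative, and shaped as documented", {
  lib1 <- build_library(seed = 5)
  lib2 <- build_library(seed = 5)
  expect_identical(lib1$spectra, lib2$spectra)
  expect_false(identical(build_library(seed = 6)$spectra, lib1$spectra))
  nb <- lib1$labels != "baseline"
  expect_true(all(lib1$spectra[, nb] >= 0))
  ## constant baseline
  expect_equal(var(lib1$spectra[, "baseline"]), 0)
  expect_error(build_library(list(min_nm = 400, max_nm = 1000, bands = 10)),
               "invalid grid")

  wl <- lib1$wavelengths_nm
  chl1 <- lib1$spectra[, "chl_1"]
  ## local maximum in the green region
  green <- which(wl >= 520 & wl <= 560)
  peak <- green[which.max(chl1[green])]
  expect_gt(chl1[peak], chl1[min(green) - 5])
  expect_gt(chl1[peak], chl1[max(green) + 5])
  ## red edge completes by 760 nm: beyond it the spectrum is near its plateau
  plateau <- mean(chl1[wl >= 800 & wl <= 900])
  expect_gt(min(chl1[wl >= 760 & wl <= 900]), 0.95 * plateau)
  ## red edge rises steeply before 760
  expect_lt(chl1[wl == 680], 0.3 * plateau)
})

test_that("the two plant components are similar but not collinear", {
  ## regression value recorded from the 301-band default grid
  lib <- build_library(seed = 1)
  cs <- cosine(lib$spectra[, "chl_1"], lib$spectra[, "chl_2"])
  expect_equal(cs, 0.9878809, tolerance = 1e-6)
  for (seed in 2:6) {
    lib <- build_library(seed = seed)
    cs <- cosine(lib$spectra[, "chl_1"], lib$spectra[, "chl_2"])
    expect_gt(cs, 0.7); expect_lt(cs, 0.999)
  }
})

test_that("rosette layouts are deterministic ellipse unions with exact counts", {
  expect_error(generate_rosette(50, 50, 0), "at least one")
  l1 <- generate_rosette(60, 60, 5, seed = 3)
  l2 <- generate_rosette(60, 60, 5, seed = 3)
  expect_identical(l1$grid, l2$grid)
  expect_identical(l1$leaf_pixel_count, sum(l1$grid))
  expect_error(generate_rosette(20, 20, 3, scale = 3, seed = 1), "overflow")

  ## single ellipse vs brute-force lattice count
  em <- ellipse_mask(40, 40, center = c(20, 20), semi_axes = c(5, 3))
  brute <- 0L
  for (r in 1:40) for (cc in 1:40)
    if (((r - 20) / 5)^2 + ((cc - 20) / 3)^2 < 1) brute <- brute + 1L
  expect_identical(sum(em), brute)
})

test_that("scene truth respects support and counting invariants", {
  lib <- build_library(seed = 2)
  lay <- generate_rosette(64, 64, 6, seed = 4)
  tr <- build_scene_truth(lib, lay, "CsCl", stress_level = 0.5,
                          background_bleed = 0, seed = 5)
  g <- tr$plant_layout
  expect_identical(tr$leaf_pixel_count, sum(g))
  for (nm in names(tr$concentration_maps))
    expect_true(all(tr$concentration_maps[[nm]] >= 0), label = nm)
  ## stress confined to the plant, background excluded from it (no bleed)
  for (nm in c("CsCl_1", "CsCl_2"))
    expect_equal(max(tr$concentration_maps[[nm]][!g]), 0)
  expect_gt(sum(tr$concentration_maps$CsCl_2[g]), 0)
  for (nm in c("bg_1", "bg_2", "bg_3"))
    expect_equal(max(tr$concentration_maps[[nm]][g]), 0)
  ## inactive stress components are zero everywhere
  trn <- build_scene_truth(lib, lay, "NaCl", stress_level = 0.5, seed = 5)
  expect_equal(max(trn$concentration_maps$CuCl2), 0)
  expect_gt(max(trn$concentration_maps$NaCl), 0)
  expect_error(build_scene_truth(lib, lay, "control", stress_level = -1),
               ">= 0")
})

test_that("noiseless render calibrates back to the exact mixture", {
  sc <- small_scene(seed = 21)
  C <- vapply(sc$truth$concentration_maps, as.vector, numeric(64 * 64))
  mix <- C %*% t(sc$library$spectra)
  got <- matrix(sc$refl$values, 64 * 64, 301)
  expect_lt(max(abs(got - mix)) / max(mix), 1e-10)
  expect_true(all(sc$acq$white_frame > sc$acq$dark_frame))
  ## all-zero truth -> identically zero reflectance
  lib <- sc$library
  lay <- generate_rosette(32, 32, 3, scale = 0.6, seed = 1)
  tr0 <- build_scene_truth(lib, lay, "control", background_bleed = 0,
                           baseline_level = 0, seed = 1)
  for (nm in names(tr0$concentration_maps))
    tr0$concentration_maps[[nm]][] <- 0
  acq0 <- render_scene(lib, tr0, 0)
  r0 <- calibrate_reflectance(acq0$raw_cube, acq0$white_frame, acq0$dark_frame)
  expect_equal(max(abs(r0$values)), 0)
  expect_error(render_scene(lib, tr0, noise_sd = -0.1), "noise_sd")
})

test_that("render noise has the requested reflectance-scale standard deviation", {
  lib <- build_library(seed = 3)
  lay <- generate_rosette(100, 100, 6, scale = 1.2, seed = 2)
  tr <- build_scene_truth(lib, lay, "control", background_bleed = 0.25,
                          seed = 3)
  clean <- render_scene(lib, tr, 0, seed = 10)
  noisy <- render_scene(lib, tr, 0.01, seed = 10)
  rc <- calibrate_reflectance(clean$raw_cube, clean$white_frame,
                              clean$dark_frame)
  rn <- calibrate_reflectance(noisy$raw_cube, noisy$white_frame,
                              noisy$dark_frame)
  diffm <- matrix(rn$values - rc$values, 100 * 100, 301)
  band_sd <- apply(diffm[, c(1, 100, 200, 301)], 2, sd)
  se <- 0.01 / sqrt(2 * (1e4 - 1))
  expect_true(all(abs(band_sd - 0.01) < 3 * se + 1e-5))
})

test_that("experiments encode growth, stress schedules, and heteroscedasticity", {
  cfg <- experiment_config(conditions = c("control", "NaCl", "CsCl", "CsCl_K"),
                           replicates = 2L, frame = c(72L, 72L),
                           rosette_scale = 1, noise_sd = 0,
                           grid = list(min_nm = 400, max_nm = 1000,
                                       bands = 101L))
  ex <- generate_experiment(cfg, seed = 31)
  conds <- vapply(ex$scenes, function(s) s$truth$condition_label, "")
  days <- vapply(ex$scenes, function(s) s$truth$day, 1L)
  ## control grows; stressed does not
  ctrl <- ex$scenes[conds == "control"]
  d0 <- vapply(ctrl[days[conds == "control"] == 0], function(s)
    s$truth$leaf_pixel_count, 1L)
  d9 <- vapply(ctrl[days[conds == "control"] == 9], function(s)
    s$truth$leaf_pixel_count, 1L)
  expect_true(all(d9 > d0))
  ## stress component counts per condition at the final day
  nz <- function(s, comp) max(s$truth$concentration_maps[[comp]]) > 0
  for (s in ex$scenes[conds == "NaCl" & days == 9]) {
    expect_true(nz(s, "NaCl"))
    expect_false(nz(s, "CuCl2") || nz(s, "CsCl_1") || nz(s, "CsCl_2"))
  }
  for (s in ex$scenes[conds == "CsCl" & days == 9])
    expect_true(nz(s, "CsCl_1") && nz(s, "CsCl_2") && !nz(s, "NaCl"))
  ## high-K arm: cesium stress amplitudes shrunk by the suppression factor
  amp <- function(s, comp) max(s$truth$concentration_maps[[comp]])
  cs <- vapply(ex$scenes[conds == "CsCl" & days == 9], amp, 1, comp = "CsCl_2")
  csk <- vapply(ex$scenes[conds == "CsCl_K" & days == 9], amp, 1,
                comp = "CsCl_2")
  expect_lt(max(csk), 0.2 * min(cs))
  ## determinism
  ex2 <- generate_experiment(cfg, seed = 31)
  expect_identical(ex$scenes[[3]]$raw_cube$values,
                   ex2$scenes[[3]]$raw_cube$values)
  expect_error(generate_experiment(
    experiment_config(conditions = "Mercury"), seed = 1), "unknown condition")
})

test_that("config round-trips through YAML with defaults for missing keys", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("conditions: [control, NaCl]", "replicates: 3",
               "noise_sd: 0.002"), path)
  cfg <- read_experiment_config(path)
  expect_identical(cfg$conditions, c("control", "NaCl"))
  expect_identical(cfg$replicates, 3L)
  expect_equal(cfg$noise_sd, 0.002)
  expect_equal(cfg$frame, experiment_config()$frame)
  writeLines("bogus_key: 1", path)
  expect_error(read_experiment_config(path), "unknown config key")
})
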