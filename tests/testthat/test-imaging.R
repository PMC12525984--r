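test_that("calibration maps the reference endpoints correctly", {
  g <- wavelength_grid(c(500, 600, 700))
  w <- reference_frame(rep(9, 3), g, "white")
  d <- reference_frame(rep(1, 3), g, "dark")
  as_cube <- function(v) raw_cube(array(v, c(2, 2, 3)), g)

  expect_equal(unique(as.vector(calibrate_cube(as_cube(9), w, d)$data)), 1)
  expect_equal(unique(as.vector(calibrate_cube(as_cube(1), w, d)$data)), 0)
  expect_equal(unique(as.vector(calibrate_cube(as_cube(5), w, d)$data)), 0.5)

  bad_w <- reference_frame(rep(1, 3), g, "white")
  expect_error(calibrate_cube(as_cube(5), bad_w, d), "pixel \\(1, 1\\), band 1")
})

test_that("calibration is linear in the raw signal (pre-clip)", {
  g <- small_grid(8)
  set.seed(11)
  dark <- array(runif(4 * 4 * 8, 90, 110), c(4, 4, 8))
  white <- dark + array(runif(4 * 4 * 8, 2500, 3000), c(4, 4, 8))
  raw <- dark + (white - dark) * array(runif(4 * 4 * 8), c(4, 4, 8))
  wf <- reference_frame(white, g, "white"); df <- reference_frame(dark, g, "dark")
  for (a in c(0.25, 0.5, 0.9)) {
    mixed <- calibrate_cube(raw_cube(a * raw + (1 - a) * dark, g), wf, df,
                            clip_max = 10)
    full <- calibrate_cube(raw_cube(raw, g), wf, df, clip_max = 10)
    expect_equal(mixed$data, a * full$data, tolerance = 1e-12)
  }
})

test_that("pseudo-colour composite separates canopy from background", {
  g <- default_grid()
  sc <- render_scene(scene_spec(noise_sd = 0, seed = 2), g)
  cal <- calibrate_cube(sc$raw, sc$white, sc$dark)
  comp <- build_pseudocolor(cal)
  expect_true(all(comp >= 0 & comp <= 1))
  fg <- sc$mask$data
  contrast <- vapply(1:3, function(ch) {
    abs(mean(comp[, , ch][fg]) - mean(comp[, , ch][!fg]))
  }, 1)
  expect_gt(max(contrast), 0.2)

  # constant cube: degenerate rescale gives an all-zero composite
  const <- reflectance_cube(array(0.4, c(4, 4, g$count)), g)
  expect_equal(unique(as.vector(build_pseudocolor(const))), 0)
})

test_that("HSV segmentation recovers the true canopy mask", {
  g <- default_grid()
  sc <- render_scene(scene_spec(noise_sd = 0.01, seed = 3), g)
  cal <- calibrate_cube(sc$raw, sc$white, sc$dark)
  comp <- build_pseudocolor(cal)

  # vacuous thresholds keep every pixel (before cleanup)
  all_px <- segment_plant(comp, c(0, 1), c(0, 1), c(0, 1), min_object_px = 1)
  expect_equal(all_px$n_foreground, prod(dim(comp)[1:2]))

  # a hue window far from green finds nothing
  expect_warning(
    none <- segment_plant(comp, h_range = c(0.90, 0.95), min_object_px = 1),
    "empty mask")
  expect_equal(none$n_foreground, 0)

  # the published thresholds recover the canopy
  m <- segment_plant(comp)
  truth <- sc$mask$data
  expect_gte(sum(m$data & truth) / sum(truth), 0.95)
  expect_lte(sum(m$data & !truth) / sum(!truth), 0.05)

  # idempotence: segmenting the already-masked composite returns the same mask
  comp2 <- comp * as.vector(m$data)
  m2 <- segment_plant(comp2)
  expect_identical(m2$data, m$data)
})

test_that("masking zeroes the background and keeps the canopy untouched", {
  g <- small_grid(6)
  cube <- reflectance_cube(array(runif(5 * 5 * 6), c(5, 5, 6)), g)
  keep <- matrix(FALSE, 5, 5); keep[2:4, 2:4] <- TRUE

  all_true <- apply_mask(cube, plant_mask(matrix(TRUE, 5, 5)))
  expect_equal(all_true$data, cube$data)

  all_false <- apply_mask(cube, plant_mask(matrix(FALSE, 5, 5)))
  expect_equal(unique(as.vector(all_false$data)), 0)

  masked <- apply_mask(cube, plant_mask(keep))
  for (b in 1:6) {
    expect_equal(masked$data[, , b][keep], cube$data[, , b][keep])
    expect_equal(unique(masked$data[, , b][!keep]), 0)
  }
  expect_error(apply_mask(cube, plant_mask(matrix(TRUE, 3, 3))), "dimensions")
})

test_that("ROI extraction averages real pixel spectra without reuse", {
  g <- small_grid(12)
  sc <- render_scene(scene_spec(40, 40, noise_sd = 0.02, seed = 5), g)
  cal <- calibrate_cube(sc$raw, sc$white, sc$dark)
  masked <- apply_mask(cal, sc$mask)

  tbl <- extract_roi_spectra(masked, n_rois = 3, roi_size_px = 25, seed = 8,
                             label = "severe")
  expect_equal(nrow(tbl$X), 3)
  expect_equal(as.character(unique(tbl$labels)), "severe")

  # ROI means equal the brute-force average of their member pixels
  m <- matrix(masked$data, prod(dim(masked$data)[1:2]), g$count)
  px <- attr(tbl, "roi_pixels")
  for (i in 1:3) {
    expect_equal(tbl$X[i, ], colMeans(m[px[[i]], ]), ignore_attr = TRUE)
  }
  # conservation: ROIs never reuse pixels and fit inside the mask
  expect_lte(length(unique(unlist(px))), masked$mask$n_foreground)
  expect_equal(length(unique(unlist(px))), 3 * 25)
  expect_true(all(masked$mask$data[unlist(px)]))

  # uniform canopy: every ROI row equals the (unique) canopy spectrum
  flat <- render_scene(scene_spec(32, 32, layout = "uniform", noise_sd = 0,
                                  seed = 2,
                                  profiles = default_stress_profiles()["control"]),
                       g)
  fm <- apply_mask(calibrate_cube(flat$raw, flat$white, flat$dark), flat$mask)
  ftbl <- extract_roi_spectra(fm, 3, 25, seed = 1)
  ctrl <- make_endmember(default_stress_profiles()$control, g)
  for (i in 1:3) expect_equal(ftbl$X[i, ], ctrl, tolerance = 1e-10,
                              ignore_attr = TRUE)

  expect_identical(extract_roi_spectra(masked, 3, 25, seed = 8)$X,
                   extract_roi_spectra(masked, 3, 25, seed = 8)$X)
  tiny_m <- matrix(FALSE, 4, 4); tiny_m[2:3, 2:3] <- TRUE
  tiny <- plant_mask(tiny_m)
  expect_error(extract_roi_spectra(
    apply_mask(reflectance_cube(array(1, c(4, 4, 12)), g), tiny), 1, 25),
    "smaller than one ROI")
})
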