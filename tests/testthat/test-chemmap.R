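# shared fixture: model trained on synthetic spectra, scene of severe plants
chemmap_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- small_grid(30)
    tbl <- stratified_split(small_table(n_per = 40, grid = g, seed = 23), seed = 23)
    pp <- preprocess_table(tbl, preprocess_spec("snv"))
    S <- pp$table
    model <- fit_plsda(S$X[S$split == "cal", ], S$labels[S$split == "cal"],
                       n_lv = 8)
    model$preprocess <- "snv"
    scene <- render_scene(scene_spec(32, 32, layout = "uniform", noise_sd = 0,
                                     profiles = default_stress_profiles()["severe"],
                                     seed = 24), g)
    masked <- apply_mask(calibrate_cube(scene$raw, scene$white, scene$dark),
                         scene$mask)
    cube <- preprocess_cube(masked, pp$spec)
    cache <<- list(g = g, model = model, scene = scene, cube = cube,
                   masked = masked)
    cache
  }
})

test_that("chemical maps are the linear scores of the model, pixel-exact", {
  fx <- chemmap_fixture()
  map <- chemical_map(fx$cube, fx$model)
  # uniform noise-free canopy: every foreground pixel carries x'beta + b
  fg <- which(fx$scene$mask$data)
  x <- matrix(fx$cube$data, 32 * 32, fx$g$count)[fg[1], ]
  expected <- as.numeric(x %*% fx$model$beta + fx$model$intercept)
  for (k in seq_along(fx$model$categories)) {
    vals <- map$score_map[, , k][fg]
    expect_equal(vals, rep(expected[k], length(fg)), tolerance = 1e-10)
    expect_true(all(is.na(map$score_map[, , k][-fg])))
  }

  # map scores agree with predict_plsda on individual pixel spectra
  m <- matrix(fx$cube$data, 32 * 32, fx$g$count)
  pred <- predict_plsda(fx$model, m[fg, , drop = FALSE])
  flat <- matrix(map$score_map, 32 * 32, length(fx$model$categories))
  expect_equal(flat[fg, ], unname(pred$scores), tolerance = 0)

  # all-zero beta degenerates to the intercepts
  zero <- fx$model
  zero$beta <- matrix(0, nrow(zero$beta), ncol(zero$beta))
  zmap <- chemical_map(fx$cube, zero)
  for (k in 1:3) {
    expect_equal(unique(zmap$score_map[, , k][fg]), zero$intercept[k])
  }
})

test_that("preprocessing provenance mismatches are a hard error", {
  fx <- chemmap_fixture()
  wrong <- fx$model
  wrong$preprocess <- "msc"
  expect_error(chemical_map(fx$cube, wrong), "preprocessing mismatch")
  expect_error(chemical_map(fx$masked, fx$model), "preprocessing mismatch")
  unmasked <- reflectance_cube(fx$cube$data, fx$g, provenance = "snv")
  expect_error(chemical_map(unmasked, fx$model), "masked")
})

test_that("thresholded labels follow the 0.5 rule and recover severity", {
  fx <- chemmap_fixture()
  map <- chemical_map(fx$cube, fx$model)
  cls <- classify_map(map)
  fg <- which(fx$scene$mask$data)
  severe_idx <- which(fx$model$categories == "severe")
  # noise-free severe plant: at least 99 % of canopy labelled severe
  expect_gte(mean(cls$label_map[fg] == severe_idx), 0.99)
  expect_equal(sum(cls$fractions), 1)
  expect_true(all(is.na(cls$label_map[-fg])))

  # synthetic score maps exercise the uncertain rule
  fake <- map
  fake$score_map[, , ] <- NA
  pix <- fg[1:2]
  fake$score_map[, , 1][pix] <- c(0.9, 0.45)
  fake$score_map[, , 2][pix] <- c(0.1, 0.40)
  fake$score_map[, , 3][pix] <- c(0.0, 0.10)
  fake$mask <- plant_mask(matrix(seq_len(32 * 32) %in% pix, 32, 32))
  fcls <- classify_map(fake)
  expect_equal(fcls$label_map[pix], c(1L, 0L))  # confident "control", uncertain
})

test_that("background values never influence foreground scores", {
  fx <- chemmap_fixture()
  map1 <- chemical_map(fx$cube, fx$model)
  tweaked <- fx$cube
  bg <- which(!fx$scene$mask$data)
  m <- matrix(tweaked$data, 32 * 32, fx$g$count)
  m[bg, ] <- 99
  tweaked$data <- array(m, dim(tweaked$data))
  map2 <- chemical_map(tweaked, fx$model)
  fg <- which(fx$scene$mask$data)
  for (k in 1:3) {
    expect_identical(map1$score_map[, , k][fg], map2$score_map[, , k][fg])
  }
})

test_that("apical severity gradient shows up in the label fractions", {
  g <- small_grid(30)
  tbl <- stratified_split(small_table(n_per = 40, grid = g, seed = 25), seed = 25)
  pp <- preprocess_table(tbl, preprocess_spec("snv"))
  model <- fit_plsda(pp$table$X[pp$table$split == "cal", ],
                     pp$table$labels[pp$table$split == "cal"], n_lv = 8)
  model$preprocess <- "snv"
  scene <- render_scene(scene_spec(48, 48, layout = "bands", noise_sd = 0.01,
                                   seed = 26), g)
  masked <- apply_mask(calibrate_cube(scene$raw, scene$white, scene$dark),
                       scene$mask)
  cls <- classify_map(chemical_map(preprocess_cube(masked, pp$spec), model))
  severe_idx <- which(model$categories == "severe")
  rows <- row(cls$label_map)
  apical <- cls$label_map[rows <= 16]; basal <- cls$label_map[rows > 32]
  frac <- function(v) mean(v[!is.na(v)] == severe_idx)
  expect_gt(frac(apical), frac(basal))
})

test_that("map rendering is deterministic and writes its colour contract", {
  fx <- chemmap_fixture()
  map <- chemical_map(fx$cube, fx$model)
  p1 <- file.path(tempdir(), "map1.png"); p2 <- file.path(tempdir(), "map2.png")
  render_map(map, p1); render_map(map, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  side <- jsonlite::read_json(paste0(p1, ".json"))
  expect_equal(side$colormap, "blue-green-yellow")
  expect_equal(side$threshold, 0.5)

  img <- png::readPNG(p1)
  fg <- which(fx$scene$mask$data)
  # severe canopy renders toward yellow/green (red+green high, blue low),
  # background black
  expect_gt(mean(img[, , 2][fg]), mean(img[, , 3][fg]))
  expect_equal(unique(as.vector(img[, , 1][-fg])), 0)
})
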