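test_that("snv standardises every spectrum", {
  expect_equal(snv(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1),
               ignore_attr = TRUE)
  set.seed(3)
  X <- matrix(rnorm(200, mean = 5, sd = 2), 10)
  S <- snv(X)
  expect_lt(max(abs(rowMeans(S))), 1e-12)
  expect_equal(apply(S, 1, sd), rep(1, 10))
  expect_equal(snv(S), S)  # idempotent
  X[3, ] <- 7
  expect_error(snv(X), "row\\(s\\): 3")
})

test_that("snv and range normalisation undo per-row affine distortions", {
  set.seed(4)
  X <- matrix(rnorm(120), 6)
  a <- runif(6, -2, 2); b <- runif(6, 0.5, 3)
  Xd <- X * b + a
  expect_equal(snv(Xd), snv(X), tolerance = 1e-12)
  expect_equal(normalize_spectra(Xd, "range"), normalize_spectra(X, "range"),
               tolerance = 1e-12)
})

test_that("msc inverts the multiplicative scatter model exactly", {
  set.seed(5)
  r <- sin(seq(0, 3, length.out = 50)) + 2
  a <- runif(8, -0.3, 0.3); b <- runif(8, 0.6, 1.6)
  X <- outer(b, r) + a
  expect_equal(msc(X, reference = r), outer(rep(1, 8), r), tolerance = 1e-10)
  # the reference itself passes through unchanged (a = 0, b = 1)
  expect_equal(msc(matrix(r, 1), reference = r), matrix(r, 1),
               tolerance = 1e-12)

  # per-row fit equals brute-force two-parameter least squares
  Xn <- X + matrix(rnorm(8 * 50, 0, 0.05), 8)
  out <- msc(Xn, reference = r)
  for (i in 1:8) {
    cf <- coef(lm(Xn[i, ] ~ r))
    expect_equal(out[i, ], (Xn[i, ] - cf[1]) / cf[2], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_error(msc(matrix(rnorm(50, sd = 1e-12), 1), reference = r), "slope")
})

test_that("savitzky-golay differentiates polynomials exactly and denoises", {
  k <- 0:39
  quad <- matrix(3 - 0.5 * k + 0.25 * k^2, 1)
  d2 <- savgol(quad, window = 11, polyorder = 3, deriv = 2)
  expect_equal(as.vector(d2), rep(2 * 0.25, 40), tolerance = 1e-9)

  const <- matrix(rep(2.5, 40), 1)
  expect_equal(savgol(const, deriv = 0), const, tolerance = 1e-12,
               ignore_attr = TRUE)

  # Monte-Carlo: smoothing shrinks white-noise variance
  set.seed(6)
  noise <- matrix(rnorm(1000 * 40), 1000)
  sm <- savgol(noise, deriv = 0)
  expect_lt(mean(apply(sm, 1, var)), mean(apply(noise, 1, var)))

  expect_error(savgol(quad, window = 10), "odd")
  expect_error(savgol(quad, window = 3, polyorder = 4), "odd")
  expect_error(savgol(matrix(1:5, 1), window = 7), "shorter")
})

test_that("row normalisations hit their fixed points", {
  expect_equal(normalize_spectra(matrix(c(2, 4, 6), 1), "range"),
               matrix(c(0, 0.5, 1), 1), ignore_attr = TRUE)
  set.seed(7)
  X <- matrix(runif(60, 0.1, 2), 6)
  expect_equal(apply(normalize_spectra(X, "max"), 1, max), rep(1, 6))
  expect_equal(rowMeans(normalize_spectra(X, "mean")), rep(1, 6))
  R <- normalize_spectra(X, "range")
  expect_true(all(R >= 0 & R <= 1))
  expect_error(normalize_spectra(matrix(0, 1, 3), "max"), "degenerate")
  expect_error(normalize_spectra(matrix(1, 1, 3), "range"), "degenerate")
})

test_that("pca matches a dense eigendecomposition and reconstructs X", {
  set.seed(8)
  X <- matrix(rnorm(60), 10, 6)
  p <- pca_spectra(X, 5)
  ev <- eigen(cov(X))$values
  expect_equal(p$explained, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_equal(sum(p$explained), 1)
  expect_equal(crossprod(p$loadings), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # completeness: scores x loadings' rebuilds centred X with all components
  full <- pca_spectra(X, 6)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_equal(full$scores %*% t(full$loadings), Xc, tolerance = 1e-10,
               ignore_attr = TRUE)

  # rank-1 data loads entirely on PC1
  r1 <- outer(rnorm(10), rnorm(6)) + 1
  expect_equal(pca_spectra(r1, 1)$explained[1], 1, tolerance = 1e-10)
  expect_error(pca_spectra(X, 7), "exceeds")
})

test_that("operators are row-independent and permutation-equivariant", {
  set.seed(9)
  X <- matrix(runif(80, 0.2, 1), 8)
  perm <- sample(8)
  for (f in list(snv, function(x) msc(x, reference = colMeans(X)),
                 function(x) savgol(x, 5, 2, 0),
                 function(x) normalize_spectra(x, "range"))) {
    expect_equal(f(X)[perm, ], f(X[perm, ]), tolerance = 1e-12)
  }
})

test_that("cube and table preprocessing agree pixel for pixel", {
  g <- small_grid(16)
  sc <- render_scene(scene_spec(24, 24, noise_sd = 0.02, seed = 4), g)
  masked <- apply_mask(calibrate_cube(sc$raw, sc$white, sc$dark), sc$mask)
  spec <- preprocess_spec("snv")
  pc <- preprocess_cube(masked, spec)
  fg <- which(masked$mask$data)[1:5]
  m_raw <- matrix(masked$data, 24 * 24, 16)
  m_pp <- matrix(pc$data, 24 * 24, 16)
  for (i in fg) {
    expect_equal(m_pp[i, ], as.vector(apply_preprocess(m_raw[i, , drop = FALSE],
                                                       spec)),
                 tolerance = 1e-12)
  }
  # background stays zero and provenance is recorded
  expect_true(all(m_pp[!masked$mask$data, ] == 0))
  expect_identical(pc$provenance, "snv")
})

test_that("msc reference freezing uses calibration rows only", {
  tbl <- stratified_split(small_table(n_per = 20, grid = small_grid(12)), seed = 2)
  out <- preprocess_table(tbl, preprocess_spec("msc"))
  expect_equal(out$spec$reference,
               colMeans(tbl$X[tbl$split == "cal", ]), ignore_attr = TRUE)
  # replaying the frozen spec reproduces the table transform bit for bit
  expect_equal(out$table$X, msc(tbl$X, reference = out$spec$reference),
               ignore_attr = TRUE)
})
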