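test_that("largest-remainder allocation reproduces the published partitions", {
  expect_equal(largest_remainder(3450), c(cal = 2070L, val = 690L, test = 690L))
  expect_equal(largest_remainder(6450), c(cal = 3870L, val = 1290L, test = 1290L))
  expect_equal(largest_remainder(6558), c(cal = 3935L, val = 1312L, test = 1311L))
  expect_equal(largest_remainder(10), c(cal = 6L, val = 2L, test = 2L))
})

test_that("stratified split is seeded, disjoint, exhaustive and proportional", {
  tbl <- small_table(n_per = 21, grid = small_grid(8))
  s1 <- stratified_split(tbl, seed = 4)
  s2 <- stratified_split(tbl, seed = 4)
  expect_identical(s1$split, s2$split)
  expect_false(identical(s1$split, stratified_split(tbl, seed = 5)$split))
  expect_false(any(s1$split == "unassigned"))
  # per category: 21 -> 13/4/4 by largest remainder, within 1 of 60/20/20
  for (cat in levels(s1$labels)) {
    alloc <- table(s1$split[s1$labels == cat])
    expect_equal(as.vector(alloc[c("cal", "val", "test")]), c(13, 4, 4))
  }
  few <- spectra_table(matrix(runif(4 * 8), 4), rep("a", 4), small_grid(8))
  expect_error(stratified_split(few), "too small")
})

test_that("full-rank PLS-DA equals multivariate least squares", {
  set.seed(14)
  X <- matrix(rnorm(30 * 5), 30)
  y <- factor(rep(c("a", "b", "c"), each = 10))
  fit <- fit_plsda(X, y, n_lv = 5)
  Y <- matrix(0, 30, 3); Y[cbind(1:30, as.integer(y))] <- 1
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  beta_ols <- solve(crossprod(Xc), crossprod(Xc, Yc))
  expect_lt(max(abs(fit$beta - beta_ols)), 1e-8)
})

test_that("PLS-DA separates separable categories and flags confidence", {
  # one informative direction, two categories
  set.seed(15)
  X <- cbind(c(rnorm(20, 0, 0.2), rnorm(20, 4, 0.2)), matrix(rnorm(40 * 3), 40))
  y <- factor(rep(c("a", "b"), each = 20))
  fit <- fit_plsda(X, y, n_lv = 1)
  pred <- predict_plsda(fit, X)
  expect_equal(mean(pred$category == y), 1)

  # arg-max and the 0.5 confidence rule
  fake <- fit
  fake$beta <- matrix(0, 4, 2, dimnames = list(NULL, c("a", "b")))
  fake$intercept <- c(0.9, 0.1)
  p <- predict_plsda(fake, matrix(0, 1, 4))
  expect_equal(as.character(p$category), "a")
  expect_true(p$confident)
  fake$intercept <- c(0.4, 0.35)
  expect_false(predict_plsda(fake, matrix(0, 1, 4))$confident)

  expect_error(predict_plsda(fit, matrix(0, 1, 7)), "band-count mismatch")
  expect_error(fit_plsda(X, y, n_lv = 10), "exceeds")  # only 4 bands
})

test_that("shrinkage LDA reproduces the closed-form discriminant", {
  # delta values equal direct evaluation of the discriminant on a toy set
  set.seed(16)
  X <- matrix(rnorm(12 * 4), 12)
  y <- factor(rep(c("a", "b", "c"), each = 4))
  fit <- fit_lda(X, y, lambda_grid = 0.1, folds = 2, seed = 1)
  d <- predict_lda(fit, X)$delta
  for (i in seq_len(nrow(X))) for (k in 1:3) {
    mu_k <- fit$mu[k, ]
    direct <- X[i, ] %*% solve(fit$sigma, mu_k) -
      0.5 * mu_k %*% solve(fit$sigma, mu_k) + log(fit$pi[k])
    expect_equal(as.numeric(d[i, k]), as.numeric(direct), tolerance = 1e-10)
  }
})

test_that("LDA boundary bisects spherical classes and chance holds for equal means", {
  tg <- two_gaussians(n = 60, sep = 6, seed = 17)
  fit <- fit_lda(tg$X, tg$y, lambda_grid = c(0, 0.1), seed = 2)
  # midpoint of the two class means is on the decision boundary
  mid <- colMeans(fit$mu)
  d_mid <- predict_lda(fit, matrix(mid, 1))$delta
  expect_equal(d_mid[1], d_mid[2], tolerance = 1e-8)
  # stepping along the mean axis flips the decision
  dir <- fit$mu[2, ] - fit$mu[1, ]
  expect_equal(as.character(predict_lda(fit, matrix(mid - 0.1 * dir, 1))$category), "a")
  expect_equal(as.character(predict_lda(fit, matrix(mid + 0.1 * dir, 1))$category), "b")

  # identical class means: accuracy near chance on balanced data
  set.seed(18)
  Xn <- matrix(rnorm(400), 200, 2)
  yn <- factor(rep(c("a", "b"), 100))
  fitn <- fit_lda(Xn, yn, lambda_grid = 0.1, seed = 3)
  acc <- mean(predict_lda(fitn, Xn)$category == yn)
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("one-vs-rest SVM matches its exported kernel-sum dual form", {
  g <- small_grid(20)
  tbl <- stratified_split(small_table(n_per = 30, grid = g, seed = 19), seed = 19)
  S <- preprocess_table(tbl, preprocess_spec("snv"))$table
  Xc <- S$X[S$split == "cal", ]; yc <- S$labels[S$split == "cal"]
  Xt <- S$X[S$split == "test", ]; yt <- S$labels[S$split == "test"]
  fit <- fit_svm_ovr(Xc, yc, cost_grid = c(1, 10), folds = 3, seed = 1)
  pred <- predict_svm_ovr(fit, Xt)
  expect_gte(mean(pred$category == yt), 0.9)
  # decision values equal the explicit sum over support vectors
  for (k in seq_along(fit$binaries)) {
    dual <- svm_decision_from_dual(fit$binaries[[k]], Xt, fit$gamma)
    expect_equal(dual, unname(pred$decision[, k]), tolerance = 1e-10)
  }

  # separable two-class data with a large cost is classified perfectly
  tg <- two_gaussians(n = 30, sep = 8, seed = 20)
  fit2 <- fit_svm_ovr(tg$X, tg$y, cost_grid = 100, gamma_grid = 0.5,
                      folds = 2, seed = 1)
  expect_equal(mean(predict_svm_ovr(fit2, tg$X)$category == tg$y), 1)

  expect_error(fit_svm_ovr(tg$X, rep("a", nrow(tg$X))), "2 categories")
})

test_that("evaluation metrics follow the confusion-matrix arithmetic", {
  perfect <- evaluate(factor(rep(c("a", "b"), each = 5)),
                      factor(rep(c("a", "b"), each = 5)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  # binary with TP=3 FN=1 FP=2 TN=4 for the positive category
  truth <- factor(c(rep("pos", 4), rep("neg", 6)), levels = c("pos", "neg"))
  pred <- factor(c("pos", "pos", "pos", "neg", "pos", "pos", rep("neg", 4)),
                 levels = c("pos", "neg"))
  ev <- evaluate(truth, pred)
  pc <- ev$per_category
  expect_equal(pc$precision[pc$category == "pos"], 0.6)
  expect_equal(pc$recall[pc$category == "pos"], 0.75)
  expect_equal(pc$f1[pc$category == "pos"], 2 * 0.6 * 0.75 / 1.35)
  expect_equal(ev$accuracy, 0.7)

  # macro F1 equals the mean of hand-computed per-category harmonic means
  set.seed(21)
  t3 <- factor(sample(c("a", "b", "c"), 60, TRUE))
  p3 <- factor(sample(c("a", "b", "c"), 60, TRUE), levels = levels(t3))
  ev3 <- evaluate(t3, p3)
  cm <- table(t3, p3)
  f1s <- vapply(1:3, function(i) {
    P <- cm[i, i] / sum(cm[, i]); R <- cm[i, i] / sum(cm[i, ])
    if (P + R == 0) 0 else 2 * P * R / (P + R)
  }, 1)
  expect_equal(ev3$f1, mean(f1s), tolerance = 1e-12)

  # never-predicted category: flagged, precision reported as 0
  expect_warning(
    ev0 <- evaluate(factor(c("a", "a", "b")), factor(c("a", "a", "a"),
                                                     levels = c("a", "b"))),
    "never predicted")
  expect_true(ev0$per_category$undefined_precision[2])
})

test_that("AUC of random scores is 1/2 and of a perfect ranker is 1", {
  set.seed(22)
  truth <- factor(sample(c("a", "b"), 1000, TRUE))
  random_scores <- matrix(runif(2000), 1000)
  ev <- evaluate(truth, factor(sample(c("a", "b"), 1000, TRUE),
                               levels = c("a", "b")), random_scores)
  expect_lt(abs(ev$auc - 0.5), 0.05)

  sep <- matrix(c(as.numeric(truth == "a"), as.numeric(truth == "b")), 1000)
  expect_equal(evaluate(truth, truth, sep)$auc, 1)
})
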