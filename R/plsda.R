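#' Fit a PLS-DA classifier
#'
#' Partial least squares discriminant analysis: the class labels are one-hot
#' encoded into a response matrix Y, and NIPALS PLS2 extracts latent
#' variables maximising X-Y covariance, `X = T P' + E_x`, `Y = U Q' + E_y`.
#' The regression coefficients `beta = W (P' W)^-1 Q'` map a (preprocessed,
#' centred) spectrum to continuous per-category scores; with as many latent
#' variables as the rank of X they coincide with multivariate least squares.
#'
#' @param X calibration spectra (N x B, already preprocessed).
#' @param labels length-N category labels.
#' @param n_lv number of latent variables (default 10, the conventional
#'   choice for these data); silently reduced, with a warning, if X runs out
#'   of rank first.
#' @param threshold score threshold stored for confidence flagging and
#'   chemical-map boundaries (default 0.5).
#' @return object of class `plsda_model` with scores/loadings/weights
#'   (`T`, `P`, `U`, `Q`, `W`), `beta` (B x C), `intercept` (C), centring
#'   vectors, `categories` and `n_lv` (effective).
#' @export
fit_plsda <- function(X, labels, n_lv = 10, threshold = 0.5) {
  X <- as_spectra_matrix(X)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 categories")
  if (n_lv > min(nrow(X) - 1, ncol(X))) stop("n_lv exceeds min(N - 1, B)")
  Y <- one_hot(y)
  xbar <- colMeans(X); ybar <- colMeans(Y)
  Xc <- sweep(X, 2, xbar); Yc <- sweep(Y, 2, ybar)

  B <- ncol(X); C <- ncol(Y)
  W <- P <- matrix(0, B, 0)
  Q <- matrix(0, C, 0)
  Tm <- Um <- matrix(0, nrow(X), 0)
  Xr <- Xc; Yr <- Yc
  a <- 0L
  while (a < n_lv) {
    u <- Yr[, which.max(colSums(Yr^2))]
    w_old <- NULL
    for (it in seq_len(500)) {
      w <- crossprod(Xr, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      t <- Xr %*% w
      q <- crossprod(Yr, t) / sum(t^2)
      u <- Yr %*% q / sum(q^2)
      if (!is.null(w_old) && sum((w - w_old)^2) < 1e-24) break
      w_old <- w
    }
    t <- Xr %*% w
    tt <- sum(t^2)
    if (tt < 1e-14 || sqrt(sum(w^2)) < 0.5) {
      warning(sprintf("rank exhausted: using %d latent variables instead of %d", a, n_lv))
      break
    }
    p <- crossprod(Xr, t) / tt
    q <- crossprod(Yr, t) / tt
    Xr <- Xr - t %*% t(p)
    Yr <- Yr - t %*% t(q)
    W <- cbind(W, w); P <- cbind(P, p); Q <- cbind(Q, q)
    Tm <- cbind(Tm, t); Um <- cbind(Um, u)
    a <- a + 1L
  }
  if (a == 0L) stop("PLS-DA failed: X has no variance")
  beta <- W %*% solve(crossprod(P, W), t(Q))
  dimnames(beta) <- list(colnames(X), levels(y))
  structure(list(
    beta = beta, intercept = as.numeric(ybar - crossprod(beta, xbar)),
    x_center = xbar, y_center = ybar,
    W = W, P = P, Q = Q, T = Tm, U = Um,
    categories = levels(y), n_lv = a, threshold = threshold,
    preprocess = NULL, bands = NULL
  ), class = "plsda_model")
}

#' Predict categories and scores from a PLS-DA model
#'
#' Continuous per-category scores are `x' beta + intercept`; the predicted
#' category is the arg-max score, and `confident` flags whether the winning
#' score clears the model's stored threshold (the conventional +/- 0.5
#' decision rule), reported alongside rather than used to veto the arg-max.
#'
#' @param model a [fit_plsda()] model.
#' @param X spectra (N x B), preprocessed identically to the calibration
#'   data (and restricted to the model's band subset, if any).
#' @return list with `scores` (N x C), `category` (factor) and `confident`
#'   (logical).
#' @export
predict_plsda <- function(model, X) {
  stopifnot(inherits(model, "plsda_model"))
  X <- as_spectra_matrix(X)
  if (ncol(X) != nrow(model$beta)) {
    stop(sprintf("band-count mismatch: model expects %d, got %d",
                 nrow(model$beta), ncol(X)))
  }
  scores <- sweep(X %*% model$beta, 2, model$intercept, `+`)
  win <- max.col(scores, ties.method = "first")
  list(scores = scores,
       category = factor(model$categories[win], levels = model$categories),
       confident = scores[cbind(seq_len(nrow(scores)), win)] > model$threshold)
}

#' Choose the PLS-DA latent-variable count by validation accuracy
#'
#' Fits models with 1..`max_lv` latent variables on the calibration set and
#' returns the count maximising validation accuracy; ties go to the
#' smallest model.
#'
#' @param Xcal,ycal calibration data. @param Xval,yval validation data.
#' @param max_lv largest candidate (default 15).
#' @return list with `n_lv`, `accuracy` (per candidate) and the refitted
#'   `model`.
#' @export
select_plsda_lv <- function(Xcal, ycal, Xval, yval, max_lv = 15) {
  Xcal <- as_spectra_matrix(Xcal); Xval <- as_spectra_matrix(Xval)
  max_lv <- min(max_lv, nrow(Xcal) - 1, ncol(Xcal))
  acc <- vapply(seq_len(max_lv), function(a) {
    fit <- suppressWarnings(fit_plsda(Xcal, ycal, n_lv = a))
    mean(predict_plsda(fit, Xval)$category == factor(yval, levels = fit$categories))
  }, 1)
  best <- which.max(acc)
  list(n_lv = best, accuracy = acc,
       model = suppressWarnings(fit_plsda(Xcal, ycal, n_lv = best)))
}

one_hot <- function(y) {
  Y <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}
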