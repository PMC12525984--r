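#' Fit a one-vs-rest RBF-kernel SVM classifier
#'
#' Trains one binary maximum-margin classifier per category (that category
#' against the rest, radial basis kernel) and classifies by the largest
#' decision value \eqn{f(x) = \sum_i \alpha_i y_i K(x_i, x) + b}. The cost
#' and kernel-width grids are searched by stratified k-fold cross-validation
#' on the calibration set (highest mean fold accuracy; ties to the first
#' grid point). The default gamma grid scales `1 / (p * mean column
#' variance)` by 0.1, 1 and 10.
#'
#' @param X calibration spectra (N x B).
#' @param labels length-N category labels (every category must leave a
#'   non-empty rest class).
#' @param cost_grid candidate costs C (default 0.1, 1, 10, 100).
#' @param gamma_grid candidate RBF widths (default scaled around
#'   `1 / (p * var)`).
#' @param folds CV folds (default 5). @param seed fold-assignment seed.
#' @return object of class `svm_ovr_model`: per-category e1071 binaries
#'   with exported support vectors, `alpha_y` dual coefficients and bias
#'   `b`, plus the chosen `(cost, gamma)` and the CV accuracy grid.
#' @export
fit_svm_ovr <- function(X, labels, cost_grid = c(0.1, 1, 10, 100),
                        gamma_grid = NULL, folds = 5, seed = 1L) {
  X <- as_spectra_matrix(X)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 categories")
  if (any(table(y) == length(y))) stop("empty rest class")
  gamma0 <- 1 / (ncol(X) * mean(apply(X, 2, var)))
  gamma_grid <- gamma_grid %||% (gamma0 * c(0.1, 1, 10))
  fold_id <- stratified_folds(y, folds, seed)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  cv_acc <- vapply(seq_len(nrow(grid)), function(gi) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- svm_ovr_core(X[tr, , drop = FALSE], y[tr],
                          grid$cost[gi], grid$gamma[gi])
      mean(predict_svm_ovr(fit, X[!tr, , drop = FALSE])$category == y[!tr])
    }, 1))
  }, 1)
  best <- which.max(cv_acc)
  model <- svm_ovr_core(X, y, grid$cost[best], grid$gamma[best])
  model$cv <- cbind(grid, accuracy = cv_acc)
  model
}

svm_ovr_core <- function(X, y, cost, gamma) {
  binaries <- lapply(levels(y), function(g) {
    yy <- factor(ifelse(y == g, "target", "rest"), levels = c("target", "rest"))
    # libsvm orients decision values toward the class seen FIRST in the
    # training rows, not the first factor level: put the target class first
    # so f(x) > 0 always means "target"
    ord <- order(yy)
    fit <- e1071::svm(X[ord, , drop = FALSE], yy[ord], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    # export the Eq-style pieces f(x) = sum(alpha_y K) + b
    list(fit = fit, sv = fit$SV, alpha_y = as.numeric(fit$coefs),
         b = -fit$rho, category = g)
  })
  structure(list(binaries = binaries, categories = levels(y),
                 cost = cost, gamma = gamma),
            class = "svm_ovr_model")
}

#' Predict from a one-vs-rest SVM
#'
#' @param model a [fit_svm_ovr()] model.
#' @param X spectra (N x B).
#' @return list with `decision` (N x C decision values) and `category`
#'   (arg-max factor).
#' @export
predict_svm_ovr <- function(model, X) {
  stopifnot(inherits(model, "svm_ovr_model"))
  X <- as_spectra_matrix(X)
  dec <- vapply(model$binaries, function(b) {
    dv <- attr(predict(b$fit, X, decision.values = TRUE), "decision.values")
    as.numeric(dv)
  }, numeric(nrow(X)))
  dec <- matrix(dec, nrow = nrow(X),
                dimnames = list(NULL, model$categories))
  win <- max.col(dec, ties.method = "first")
  list(decision = dec,
       category = factor(model$categories[win], levels = model$categories))
}

#' Evaluate an SVM decision value from its exported dual form
#'
#' Computes \eqn{f(x) = \sum_i \alpha_i y_i K(x_i, x) + b} directly from the
#' exported support vectors of one binary classifier -- the transparent
#' kernel-sum form, useful for verifying the fitted machines.
#'
#' @param binary one element of `model$binaries`.
#' @param X query spectra. @param gamma RBF width of the model.
#' @return numeric decision values.
#' @export
svm_decision_from_dual <- function(binary, X, gamma) {
  X <- as_spectra_matrix(X)
  K <- exp(-gamma * outer(rowSums(X^2), rowSums(binary$sv^2), `+`) +
             2 * gamma * tcrossprod(X, binary$sv))
  as.numeric(K %*% binary$alpha_y + binary$b)
}
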