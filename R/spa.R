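#' Successive projections chain from one starting band
#'
#' Forward variable selection with minimal collinearity: starting from band
#' `start`, every remaining column is repeatedly replaced by its component
#' orthogonal to the span of the chosen columns, and the column of maximal
#' Euclidean norm is appended (ties to the lowest index). Columns already in
#' the span project to zero and can never be selected.
#'
#' @param X numeric N x B matrix; columns should be centred (and typically
#'   standardised) beforehand.
#' @param start starting band index.
#' @param k chain length, `1 <= k <= min(N - 1, B)`.
#' @return integer vector of band indices, beginning with `start`. If the
#'   attainable rank is below `k`, the chain is truncated with a warning.
#' @export
spa_chain <- function(X, start, k) {
  X <- as_spectra_matrix(X)
  B <- ncol(X)
  stopifnot(start >= 1, start <= B)
  if (k < 1 || k > min(nrow(X) - 1, B)) {
    stop("k must satisfy 1 <= k <= min(N - 1, B)")
  }
  chain <- integer(k)
  chain[1] <- as.integer(start)
  R <- X
  for (step in seq_len(k - 1)) {
    v <- R[, chain[step]]
    nv <- sum(v^2)
    if (nv < 1e-24) {
      warning(sprintf("chain truncated at length %d: remaining columns span exhausted", step))
      return(chain[seq_len(step)])
    }
    # deflate every column by its projection on the newly chosen direction
    R <- R - outer(v, as.vector(crossprod(R, v)) / nv)
    norms <- colSums(R^2)
    norms[chain[seq_len(step)]] <- -1
    best <- which.max(norms)  # first index wins ties
    if (norms[best] < 1e-24) {
      warning(sprintf("chain truncated at length %d: remaining columns span exhausted", step))
      return(chain[seq_len(step)])
    }
    chain[step + 1] <- as.integer(best)
  }
  chain
}

#' SPA wavelength selection scored by validation accuracy
#'
#' Builds a projection chain from every candidate start, scores each prefix
#' of length `k_min..k_max` by the validation accuracy of a PLS-DA fitted on
#' those bands, and returns the best (start, k). Ties resolve to the smaller
#' subset, then the lower start. Columns are standardised (calibration mean
#' and SD) before the projections.
#'
#' @param Xcal,ycal calibration spectra and labels.
#' @param Xval,yval validation spectra and labels.
#' @param k_min,k_max subset size range (`k_min >= 2`); `k_max` above
#'   `Ncal - 1` is clipped with a warning.
#' @param starts candidate starting bands (default: all bands). Subsampling
#'   the starts trades a little optimality for speed.
#' @param n_lv latent variables of the scoring PLS-DA (rank-limited;
#'   default 10).
#' @return object of class `selection_result`: `selected_indices`,
#'   `selected_wavelengths_nm` (when a grid is supplied), `k`, `score`,
#'   `criterion_name` and the full `criterion_trace` data frame
#'   (start, k, score).
#' @param grid optional [wavelength_grid()] used to report wavelengths.
#' @export
spa_select <- function(Xcal, ycal, Xval, yval, k_min = 2, k_max = 15,
                       starts = NULL, n_lv = 10, grid = NULL) {
  Xcal <- as_spectra_matrix(Xcal); Xval <- as_spectra_matrix(Xval)
  ycal <- factor(ycal); yval <- factor(yval, levels = levels(ycal))
  stopifnot(nrow(Xcal) == length(ycal), nrow(Xval) == length(yval))
  if (k_min < 2) stop("k_min must be >= 2")
  if (k_max > nrow(Xcal) - 1) {
    warning("k_max clipped to Ncal - 1")
    k_max <- nrow(Xcal) - 1
  }
  if (k_max < k_min) stop("empty k range")
  B <- ncol(Xcal)
  starts <- starts %||% seq_len(B)

  mu <- colMeans(Xcal)
  sdv <- apply(Xcal, 2, sd)
  sdv[sdv == 0] <- 1
  Z <- scale(Xcal, mu, sdv)

  trace <- vector("list", length(starts) * (k_max - k_min + 1))
  ti <- 0L
  best <- list(score = -Inf, k = Inf, start = Inf, bands = NULL)
  for (s in starts) {
    chain <- suppressWarnings(spa_chain(Z, s, min(k_max, min(nrow(Z) - 1, B))))
    for (k in k_min:k_max) {
      if (length(chain) < k) next
      bands <- sort(chain[seq_len(k)])
      fit <- fit_plsda(Xcal[, bands, drop = FALSE], ycal,
                       n_lv = min(n_lv, k, nrow(Xcal) - 1))
      acc <- mean(predict_plsda(fit, Xval[, bands, drop = FALSE])$category == yval)
      ti <- ti + 1L
      trace[[ti]] <- data.frame(start = s, k = k, score = acc)
      if (acc > best$score ||
          (acc == best$score && (k < best$k || (k == best$k && s < best$start)))) {
        best <- list(score = acc, k = k, start = s, bands = bands)
      }
    }
  }
  structure(list(
    selected_indices = best$bands,
    selected_wavelengths_nm = if (!is.null(grid)) grid$wavelengths_nm[best$bands],
    k = best$k, start = best$start, score = best$score,
    criterion_name = "plsda_validation_accuracy",
    criterion_trace = do.call(rbind, trace[seq_len(ti)])
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d bands (start %d), %s = %.4f\n",
              x$k, x$start, x$criterion_name, x$score))
  if (!is.null(x$selected_wavelengths_nm)) {
    cat(" ", paste(sprintf("%.1f", x$selected_wavelengths_nm), collapse = ", "), "nm\n")
  }
  invisible(x)
}
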