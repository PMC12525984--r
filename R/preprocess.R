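#' Standard normal variate transform
#'
#' Centres and scales each spectrum (row) to mean 0 and unit sample
#' standard deviation, removing per-spectrum multiplicative scatter and
#' baseline offsets.
#'
#' @param X numeric N x B matrix of spectra (rows).
#' @return transformed matrix of the same shape.
#' @examples
#' snv(matrix(c(1, 2, 3), 1))  # -1 0 1
#' @export
snv <- function(X) {
  X <- as_spectra_matrix(X)
  s <- apply(X, 1, sd)
  if (any(s == 0)) {
    stop(sprintf("snv: zero-variance row(s): %s",
                 paste(which(s == 0), collapse = ", ")))
  }
  (X - rowMeans(X)) / s
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a + b * reference`
#' (ordinary least squares), and returns `(x - a) / b`. Rows generated as
#' exact affine distortions of the reference are restored exactly. The
#' reference should be frozen from the calibration rows and reused for
#' validation/test spectra and cube pixels (see [preprocess_spec()]).
#'
#' @param X numeric N x B matrix of spectra.
#' @param reference length-B reference spectrum; default the column mean of
#'   `X`.
#' @return corrected matrix of the same shape.
#' @export
msc <- function(X, reference = NULL) {
  X <- as_spectra_matrix(X)
  reference <- reference %||% colMeans(X)
  if (length(reference) != ncol(X)) stop("msc: reference has wrong length")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom == 0) stop("msc: constant reference")
  # closed-form per-row simple regression on the common reference
  b <- as.vector(X %*% rc) / denom
  a <- rowMeans(X) - b * mean(reference)
  if (any(abs(b) < 1e-8)) {
    stop(sprintf("msc: near-zero slope for row(s): %s",
                 paste(which(abs(b) < 1e-8), collapse = ", ")))
  }
  (X - a) / b
}

#' Savitzky-Golay filtering of spectra
#'
#' Local least-squares polynomial filtering along each spectrum:
#' `deriv = 0` smooths, `deriv = 2` returns the second derivative (in
#' band-index units). Boundaries are handled by the polynomial fits of the
#' first/last windows, so a polynomial of degree <= `polyorder` is
#' reproduced (or differentiated) exactly everywhere.
#'
#' @param X numeric N x B matrix of spectra.
#' @param window odd filter length, > `polyorder` (default 11).
#' @param polyorder polynomial degree (default 2 for smoothing, use 3 with
#'   `deriv = 2`).
#' @param deriv derivative order, 0 or 2.
#' @return filtered matrix of the same shape.
#' @export
savgol <- function(X, window = 11, polyorder = if (deriv == 0) 2 else 3,
                   deriv = 0) {
  X <- as_spectra_matrix(X)
  if (!deriv %in% c(0, 2)) stop("deriv must be 0 or 2")
  if (window %% 2 != 1 || window <= polyorder) {
    stop("window must be odd and greater than polyorder")
  }
  if (ncol(X) < window) stop("spectra shorter than filter window")
  t(apply(X, 1, signal::sgolayfilt, p = polyorder, n = window, m = deriv))
}

#' Row-wise spectrum normalisation
#'
#' `max`: divide by the row maximum; `mean`: divide by the row mean;
#' `range`: map linearly onto [0, 1].
#'
#' @param X numeric N x B matrix of spectra.
#' @param mode `"max"`, `"mean"` or `"range"`.
#' @return normalised matrix.
#' @export
normalize_spectra <- function(X, mode = c("max", "mean", "range")) {
  mode <- match.arg(mode)
  X <- as_spectra_matrix(X)
  bad_rows <- function(cond) {
    if (any(cond)) stop(sprintf("normalize (%s): degenerate row(s): %s",
                                mode, paste(which(cond), collapse = ", ")))
  }
  switch(mode,
    max = {
      mx <- apply(X, 1, max); bad_rows(mx == 0); X / mx
    },
    mean = {
      mn <- rowMeans(X); bad_rows(mn == 0); X / mn
    },
    range = {
      lo <- apply(X, 1, min); hi <- apply(X, 1, max)
      bad_rows(hi == lo); (X - lo) / (hi - lo)
    })
}

#' Principal component analysis of spectra
#'
#' Column-mean-centred PCA (no scaling), as used for score-plot
#' visualisation of treatment separation.
#'
#' @param X numeric N x B matrix.
#' @param n_components number of components to return.
#' @return list with `scores` (N x k), `loadings` (B x k, orthonormal) and
#'   `explained` (variance fractions of ALL components, non-increasing,
#'   summing to 1).
#' @export
pca_spectra <- function(X, n_components = 2) {
  X <- as_spectra_matrix(X)
  if (n_components < 1 || nrow(X) <= n_components) {
    stop("need N > n_components >= 1")
  }
  if (n_components > min(nrow(X) - 1, ncol(X))) {
    stop("n_components exceeds min(N - 1, B)")
  }
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       loadings = p$rotation[, seq_len(n_components), drop = FALSE],
       explained = ev / sum(ev))
}

#' Preprocessing specification
#'
#' A serialisable description of one preprocessing operator, so that the
#' identical transform can be replayed on validation/test spectra and,
#' pixel-wise, on image cubes at chemical-imaging time.
#'
#' @param name one of `"raw"`, `"snv"`, `"msc"`, `"sg_smooth"`, `"sg_2nd"`,
#'   `"max_norm"`, `"mean_norm"`, `"range_norm"`.
#' @param window,polyorder Savitzky-Golay parameters (window odd,
#'   > polyorder).
#' @param reference frozen MSC reference spectrum (filled in automatically
#'   from calibration rows by [preprocess_table()]).
#' @return object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(name = c("raw", "snv", "msc", "sg_smooth", "sg_2nd",
                                     "max_norm", "mean_norm", "range_norm"),
                            window = 11,
                            polyorder = if (name == "sg_2nd") 3 else 2,
                            reference = NULL) {
  name <- match.arg(name)
  if (window %% 2 != 1 || window <= polyorder) {
    stop("window must be odd and greater than polyorder")
  }
  structure(list(name = name, window = window, polyorder = polyorder,
                 reference = reference),
            class = "preprocess_spec")
}

#' Apply a preprocessing spec to a matrix of spectra
#'
#' @param X numeric N x B matrix.
#' @param spec a [preprocess_spec()].
#' @return transformed matrix.
#' @export
apply_preprocess <- function(X, spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  switch(spec$name,
    raw = as_spectra_matrix(X),
    snv = snv(X),
    msc = msc(X, reference = spec$reference),
    sg_smooth = savgol(X, spec$window, spec$polyorder, deriv = 0),
    sg_2nd = savgol(X, spec$window, spec$polyorder, deriv = 2),
    max_norm = normalize_spectra(X, "max"),
    mean_norm = normalize_spectra(X, "mean"),
    range_norm = normalize_spectra(X, "range"))
}

#' Preprocess a spectra table, freezing data-dependent parameters
#'
#' Applies the operator to every row. For MSC with no stored reference, the
#' reference is computed from the calibration rows only (all rows if the
#' table is unsplit) and frozen into the returned spec so later data sees
#' the identical transform without leakage.
#'
#' @param tbl a [spectra_table()].
#' @param spec a [preprocess_spec()].
#' @return list with `table` (transformed [spectra_table()], provenance
#'   extended) and `spec` (the spec, with any frozen reference filled in).
#' @export
preprocess_table <- function(tbl, spec) {
  stopifnot(inherits(tbl, "spectra_table"), inherits(spec, "preprocess_spec"))
  if (spec$name == "msc" && is.null(spec$reference)) {
    cal <- tbl$X[tbl$split == "cal", , drop = FALSE]
    if (nrow(cal) == 0) cal <- tbl$X
    spec$reference <- colMeans(cal)
  }
  out <- spectra_table(apply_preprocess(tbl$X, spec), tbl$labels, tbl$grid,
                       split = as.character(tbl$split),
                       provenance = c(tbl$provenance, preprocess_tag(spec)))
  list(table = out, spec = spec)
}

#' Preprocess a cube pixel-wise
#'
#' Applies the operator to every pixel spectrum (foreground pixels only if
#' the cube is masked; background stays zero), recording provenance so
#' chemical imaging can verify the cube matches its model.
#'
#' @param cube a [reflectance_cube()].
#' @param spec a [preprocess_spec()] (for MSC the reference must already be
#'   frozen).
#' @return transformed [reflectance_cube()].
#' @export
preprocess_cube <- function(cube, spec) {
  stopifnot(inherits(cube, "reflectance_cube"), inherits(spec, "preprocess_spec"))
  if (spec$name == "msc" && is.null(spec$reference)) {
    stop("preprocess_cube needs an msc spec with a frozen reference")
  }
  m <- cube_to_matrix(cube)
  if (!is.null(cube$mask)) {
    fg <- which(cube$mask$data)
    m[fg, ] <- apply_preprocess(m[fg, , drop = FALSE], spec)
  } else {
    m <- apply_preprocess(m, spec)
  }
  d <- dim(cube$data)
  reflectance_cube(matrix_to_cube_data(m, d[1], d[2]), cube$grid,
                   mask = cube$mask,
                   provenance = c(cube$provenance, preprocess_tag(spec)))
}

preprocess_tag <- function(spec) {
  if (spec$name %in% c("sg_smooth", "sg_2nd")) {
    sprintf("%s(w=%d,p=%d)", spec$name, spec$window, spec$polyorder)
  } else spec$name
}

as_spectra_matrix <- function(X) {
  if (inherits(X, "spectra_table")) X <- X$X
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  storage.mode(X) <- "double"
  X
}
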