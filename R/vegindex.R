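#' Narrowband vegetation indices
#'
#' Computes NDVI, RDVI, GNDVI and MCARI from reflectance at the
#' conventional narrowband positions (red 670 nm, green 550 nm, red-edge
#' 700 nm, NIR 800 nm, resolved via [nearest_band()]):
#' \deqn{NDVI = (NIR - Red) / (NIR + Red)}
#' \deqn{RDVI = (NIR - Red) / \sqrt{NIR + Red}}
#' \deqn{GNDVI = (NIR - Green) / (NIR + Green)}
#' \deqn{MCARI = ((\rho_{700} - \rho_{670}) - 0.2 (\rho_{700} - \rho_{550}))
#'   (\rho_{700} / \rho_{670})}
#'
#' @param x a [spectra_table()], numeric matrix of spectra, or
#'   [reflectance_cube()].
#' @param grid [wavelength_grid()] (taken from `x` when available).
#' @param rdvi_as_printed if TRUE, RDVI uses the plain `(NIR + Red)`
#'   denominator (i.e. duplicates NDVI) as sometimes typeset; default FALSE
#'   uses the standard square-root form.
#' @return for tabular input, a data frame with columns `NDVI`, `RDVI`,
#'   `GNDVI`, `MCARI` and `treatment`; for a cube, a named list of four
#'   H x W index maps (background NA when the cube is masked). Samples with
#'   a zero denominator yield NaN with a warning.
#' @export
compute_indices <- function(x, grid = NULL, rdvi_as_printed = FALSE) {
  if (inherits(x, "reflectance_cube")) {
    m <- cube_to_matrix(x)
    idx <- index_values(m, x$grid, rdvi_as_printed)
    h <- dim(x$data)[1]; w <- dim(x$data)[2]
    maps <- lapply(idx, function(v) {
      mp <- matrix(v, h, w)
      if (!is.null(x$mask)) mp[!x$mask$data] <- NA_real_
      mp
    })
    return(maps)
  }
  labels <- NULL
  if (inherits(x, "spectra_table")) {
    grid <- x$grid; labels <- x$labels; x <- x$X
  }
  if (is.null(grid)) stop("grid required for matrix input")
  out <- as.data.frame(index_values(as_spectra_matrix(x), grid, rdvi_as_printed))
  out$treatment <- labels %||% factor(rep(NA_character_, nrow(out)))
  out
}

index_values <- function(m, grid, rdvi_as_printed) {
  b <- vapply(c(red = 670, green = 550, edge = 700, nir = 800),
              function(t) nearest_band(grid, t), 1L)
  red <- m[, b["red"]]; green <- m[, b["green"]]
  p700 <- m[, b["edge"]]; nir <- m[, b["nir"]]
  div <- function(num, den) {
    bad <- den == 0
    if (any(bad)) warning(sprintf("%d sample(s) with zero denominator -> NaN", sum(bad)))
    out <- num / den
    out[bad] <- NaN
    out
  }
  list(
    NDVI = div(nir - red, nir + red),
    RDVI = if (rdvi_as_printed) div(nir - red, nir + red)
           else div(nir - red, sqrt(pmax(nir + red, 0))),
    GNDVI = div(nir - green, nir + green),
    MCARI = ((p700 - red) - 0.2 * (p700 - green)) * div(p700, red)
  )
}

#' One-way ANOVA with Duncan's multiple range grouping
#'
#' Fits a one-way ANOVA across treatments and assigns Duncan multiple-range
#' letter groups: treatments sharing a letter are not significantly
#' different at `alpha`. The least significant range for a span of `p`
#' ordered means is `q(p, df; alpha_p) * sqrt(MSE / n_h)` with the Duncan
#' protection level `alpha_p = 1 - (1 - alpha)^(p - 1)` (studentized-range
#' quantile) and `n_h` the harmonic mean group size.
#'
#' @param values numeric response vector (NaN/NA dropped with their group).
#' @param treatments group labels, >= 2 groups with >= 2 members each.
#' @param alpha significance level (default 0.05).
#' @param checks if TRUE, also report Shapiro-Wilk normality of residuals
#'   and (if the car package is installed) Levene homogeneity; reporting
#'   only, never gating.
#' @return object of class `duncan_result`: data frame `groups` (treatment,
#'   n, mean, letters; ordered by decreasing mean), `F`, `p_value`, `df`,
#'   `mse`, `alpha`, optional `checks`.
#' @export
anova_duncan <- function(values, treatments, alpha = 0.05, checks = FALSE) {
  keep <- is.finite(values)
  values <- values[keep]
  treatments <- factor(treatments[keep])
  treatments <- droplevels(treatments)
  n <- table(treatments)
  if (nlevels(treatments) < 2) stop("need at least 2 treatments")
  if (any(n < 2)) stop("each treatment needs at least 2 members")
  fit <- aov(values ~ treatments)
  an <- summary(fit)[[1]]
  rn <- trimws(rownames(an))
  mse <- an[rn == "Residuals", "Mean Sq"]
  df_err <- an[rn == "Residuals", "Df"]
  if (mse <= 1e-20 * max(1, mean(values^2))) {
    stop("zero within-group variance: Duncan ranges undefined")
  }
  Fstat <- an[1, "F value"]
  pval <- an[1, "Pr(>F)"]

  means <- tapply(values, treatments, mean)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  nh <- k / sum(1 / as.numeric(n))  # harmonic mean group size
  se <- sqrt(mse / nh)
  # least significant range for spans 2..k
  lsr <- c(NA, vapply(2:k, function(p) {
    qtukey((1 - alpha)^(p - 1), nmeans = p, df = df_err) * se
  }, 1))

  homogeneous <- function(i, j) (m[i] - m[j]) <= lsr[j - i + 1]
  # maximal homogeneous intervals over the ordered means get one letter each
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && homogeneous(i, j + 1)) j <- j + 1
    intervals[[i]] <- c(i, j)
  }
  maximal <- Filter(function(iv) {
    !any(vapply(intervals, function(o) {
      (o[1] < iv[1] && o[2] >= iv[2]) || (o[1] <= iv[1] && o[2] > iv[2])
    }, TRUE))
  }, intervals)
  maximal <- unique(maximal)
  letter_of <- vapply(seq_along(maximal), function(ii) letters[ii], "")
  lab <- vapply(seq_len(k), function(i) {
    paste0(letter_of[vapply(maximal, function(iv) i >= iv[1] && i <= iv[2], TRUE)],
           collapse = "")
  }, "")

  groups <- data.frame(treatment = names(m), n = as.integer(n[ord]),
                       mean = as.numeric(m), letters = lab,
                       row.names = NULL)
  out <- list(groups = groups, F = Fstat, p_value = pval,
              df = c(an[1, "Df"], df_err), mse = mse, alpha = alpha)
  if (checks) {
    res <- stats::residuals(fit)
    sw <- if (length(res) >= 3 && length(res) <= 5000)
      stats::shapiro.test(res) else NULL
    lv <- if (requireNamespace("car", quietly = TRUE))
      car::leveneTest(values ~ treatments) else NULL
    out$checks <- list(shapiro = sw, levene = lv)
  }
  structure(out, class = "duncan_result")
}

#' @export
print.duncan_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g; Duncan letters at alpha = %g\n",
              x$df[1], x$df[2], x$F, x$p_value, x$alpha))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
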