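#' Labelled spectra table
#'
#' N x B matrix of reflectance spectra with a severity label and a split
#' assignment per row. The central tabular object of the analysis: ROI
#' extraction produces one, the classifiers consume one.
#'
#' @param X numeric N x B matrix, no NA.
#' @param labels length-N category labels (coerced to factor).
#' @param grid a [wavelength_grid()] with `count == ncol(X)`.
#' @param split length-N split assignment in cal/val/test/unassigned
#'   (default all unassigned).
#' @param provenance character vector recording applied preprocessing, in
#'   order.
#' @return object of class `spectra_table`.
#' @export
spectra_table <- function(X, labels, grid,
                          split = rep("unassigned", nrow(X)),
                          provenance = character()) {
  stopifnot(is.matrix(X), inherits(grid, "wavelength_grid"))
  if (ncol(X) != grid$count) stop("spectra have wrong band count for grid")
  if (anyNA(X) || any(!is.finite(X))) stop("spectra table must be finite, no NA")
  if (length(labels) != nrow(X)) stop("one label per row required")
  split <- factor(split, levels = c("cal", "val", "test", "unassigned"))
  if (anyNA(split)) stop("split values must be cal/val/test/unassigned")
  colnames(X) <- sprintf("%.1f", grid$wavelengths_nm)
  structure(list(X = X, labels = factor(labels), split = split,
                 grid = grid, provenance = provenance),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d spectra x %d bands\n", nrow(x$X), ncol(x$X)))
  print(table(category = x$labels, split = x$split))
  if (length(x$provenance)) cat("preprocessing:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Sample a labelled synthetic spectra table
#'
#' Draws `counts[k]` spectra per severity category. Each row is that
#' category's endmember distorted by a per-row multiplicative/additive
#' scatter (slope and offset drawn uniformly from the given ranges, the
#' distortion SNV and MSC are designed to remove) and then per-band Gaussian
#' noise. Rows emulate ROI-mean spectra -- the average of a ~25-pixel canopy
#' patch -- so the default noise SD is the pixel-level 0.01 attenuated by
#' the patch average, 0.01 / sqrt(25) = 0.002.
#'
#' @param counts named integer vector of per-category row counts; names must
#'   match `names(profiles)`.
#' @param profiles list of [stress_profile()]s (default
#'   [default_stress_profiles()]).
#' @param grid a [wavelength_grid()].
#' @param seed integer RNG seed.
#' @param scatter_slope,scatter_offset length-2 uniform ranges of the
#'   per-row scatter distortion.
#' @param noise_sd per-band Gaussian noise SD (reflectance units).
#' @return a [spectra_table()] with N = `sum(counts)` rows.
#' @examples
#' tbl <- sample_spectra_table(c(control = 5, early = 5, severe = 5), seed = 1)
#' table(tbl$labels)
#' @export
sample_spectra_table <- function(counts,
                                 profiles = default_stress_profiles(),
                                 grid = default_grid(), seed = 1L,
                                 scatter_slope = c(0.8, 1.2),
                                 scatter_offset = c(-0.05, 0.05),
                                 noise_sd = 0.002) {
  if (length(counts) == 0) stop("empty design: counts must name at least one category")
  if (is.null(names(counts)) || !all(names(counts) %in% names(profiles))) {
    stop("counts must be named after profiles")
  }
  if (any(counts < 1)) stop("each category needs at least one spectrum")
  stopifnot(inherits(grid, "wavelength_grid"))
  B <- grid$count
  N <- sum(counts)
  ends <- lapply(profiles[names(counts)], make_endmember, grid = grid)
  X <- with_seed(seed, {
    m <- matrix(NA_real_, N, B)
    row0 <- 0L
    for (k in seq_along(counts)) {
      n_k <- counts[[k]]
      slope <- runif(n_k, scatter_slope[1], scatter_slope[2])
      offset <- runif(n_k, scatter_offset[1], scatter_offset[2])
      base <- matrix(rep(ends[[k]], each = n_k), n_k) * slope + offset
      if (noise_sd > 0) base <- base + matrix(rnorm(n_k * B, 0, noise_sd), n_k)
      m[row0 + seq_len(n_k), ] <- base
      row0 <- row0 + n_k
    }
    m
  })
  spectra_table(X, rep(names(counts), counts), grid)
}

#' Write / read a spectra table as CSV
#'
#' Columns: `sample_id`, `category`, `split`, then one column per wavelength
#' (header = wavelength in nm with 1 decimal).
#'
#' @param tbl a [spectra_table()].
#' @param path CSV file path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a [spectra_table()].
#' @export
write_spectra_csv <- function(tbl, path) {
  stopifnot(inherits(tbl, "spectra_table"))
  df <- data.frame(sample_id = seq_len(nrow(tbl$X)),
                   category = as.character(tbl$labels),
                   split = as.character(tbl$split),
                   tbl$X, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wl <- as.numeric(names(df)[-(1:3)])
  spectra_table(as.matrix(df[, -(1:3), drop = FALSE]), df$category,
                wavelength_grid(wl), split = df$split)
}
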