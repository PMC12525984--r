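#' Wavelength grid of a hyperspectral sensor
#'
#' A `wavelength_grid` records the band-centre wavelengths (nm) of a cube or
#' spectra table. Centres must be strictly increasing and lie in the VNIR
#' window 400--1000 nm.
#'
#' @param wavelengths_nm numeric vector of band centres in nm, strictly
#'   increasing, length >= 2.
#' @return an object of class `wavelength_grid` with fields `wavelengths_nm`
#'   and `count`.
#' @examples
#' g <- default_grid()
#' g$count
#' @export
wavelength_grid <- function(wavelengths_nm) {
  w <- as.numeric(wavelengths_nm)
  if (length(w) < 2) stop("wavelength grid needs at least 2 bands")
  if (any(!is.finite(w))) stop("wavelength grid must be finite")
  if (any(diff(w) <= 0)) stop("wavelengths must be strictly increasing")
  if (w[1] < 400 || w[length(w)] > 1000) {
    stop("wavelengths must lie within 400-1000 nm (VNIR)")
  }
  structure(list(wavelengths_nm = w, count = length(w)),
            class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d bands, %.1f-%.1f nm\n",
              x$count, x$wavelengths_nm[1], x$wavelengths_nm[x$count]))
  invisible(x)
}

#' Default VNIR working grid
#'
#' 194 evenly spaced band centres spanning 511--900 nm, matching the band
#' count and endpoints of the Senop HSC-2 frame sensor. The true sensor
#' centres are slightly non-uniform; the published subset is available as
#' [senop_known_wavelengths()] for band-lookup work.
#'
#' @param count number of bands (default 194).
#' @return a [wavelength_grid()].
#' @export
default_grid <- function(count = 194) {
  wavelength_grid(seq(511, 900, length.out = count))
}

#' Published Senop HSC-2 band centres
#'
#' The subset of HSC-2 band-centre wavelengths (nm) that appear in the
#' published band-selection tables and methods text for the greenhouse
#' potato / sweet-potato stress experiments. The full 194-centre table is not
#' public; this sorted union of printed centres supports wavelength lookup
#' fixtures (e.g. "the red band at 670 nm is 669.6 or 671.7 nm").
#'
#' @return numeric vector of wavelengths in nm.
#' @export
senop_known_wavelengths <- function() {
  sort(unique(c(
    # band-selection table lists
    516.1, 556.5, 564.6, 568.6, 576.7, 594.9, 603, 613.1, 617.1, 619.1,
    625.2, 627.2, 631.2, 637.3, 649.4, 655.5, 659.5, 665.6, 671.7, 675.7,
    693.9, 699.9, 702, 708, 710.1, 714.1, 716.1, 724.2, 728.2, 732.3, 734.3,
    736.3, 740.4, 742.4, 744.4, 746.4, 748.4, 750.5, 752.5, 754.5, 758.5,
    760.6, 762.6, 764.6, 766.6, 768.7, 770.7, 772.7, 776.7, 778.8, 780.8,
    782.8, 784.8, 786.8, 788.9, 790.9, 794.9, 796.9, 799, 801, 803, 805,
    807, 809.1, 813.1, 815.1, 817.2, 819.2, 821.2, 823.2, 825.2, 827.3,
    829.3, 831.3, 833.3, 837.4, 839.4, 841.4, 843.4, 845.4, 847.5, 851.5,
    853.5, 855.5, 857.6, 859.6, 861.6, 863.6, 865.6, 869.7, 871.7, 873.7,
    875.8, 877.8, 879.8, 881.8, 883.8, 885.9, 887.9, 891.9, 893.9, 896, 898,
    # centres quoted in the methods text (index bands, pseudo-colour)
    550.4, 552.4, 669.6, 679.7
  )))
}

#' Nearest band index for a target wavelength
#'
#' @param grid a [wavelength_grid()].
#' @param target_nm target wavelength in nm.
#' @return integer band index (1-based) minimising the absolute distance to
#'   `target_nm`; exact distance ties resolve to the lower wavelength.
#' @details Targets farther outside the grid range than half the mean band
#'   spacing raise an error.
#' @examples
#' nearest_band(default_grid(), 670)
#' @export
nearest_band <- function(grid, target_nm) {
  stopifnot(inherits(grid, "wavelength_grid"), is.numeric(target_nm),
            length(target_nm) == 1, is.finite(target_nm))
  w <- grid$wavelengths_nm
  half_spacing <- mean(diff(w)) / 2
  if (target_nm < w[1] - half_spacing || target_nm > w[grid$count] + half_spacing) {
    stop(sprintf("target %.1f nm outside grid range %.1f-%.1f nm",
                 target_nm, w[1], w[grid$count]))
  }
  d <- abs(w - target_nm)
  # which.min returns the first (lower-wavelength) index on exact ties
  as.integer(which.min(d))
}
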