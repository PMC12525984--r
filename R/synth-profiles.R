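#' Stress-severity spectral profile
#'
#' Parameterises how abiotic stress distorts a healthy canopy reflectance
#' spectrum: pigment loss lifts visible reflectance (`vis_gain` multiplies
#' 520--700 nm), structural/water damage lowers the NIR plateau (`nir_loss`
#' multiplies 740--900 nm), the red-edge inflection slides by
#' `rededge_shift_nm` (negative = toward blue, the usual stress response),
#' and leaf-water absorption features near 742 and 842 nm shallow out as
#' tissue dries (`water_band_depth`).
#'
#' @param category_label severity category name, e.g. "control".
#' @param vis_gain multiplicative lift of visible reflectance, must be > 0;
#'   1 for an unstressed plant.
#' @param nir_loss multiplicative drop of NIR reflectance, must be > 0;
#'   1 for an unstressed plant.
#' @param rededge_shift_nm shift of the red-edge inflection point (nm).
#' @param water_band_depth depth of the Gaussian water absorptions
#'   (reflectance units, >= 0).
#' @return object of class `stress_profile`.
#' @export
stress_profile <- function(category_label, vis_gain = 1, nir_loss = 1,
                           rededge_shift_nm = 0, water_band_depth = 0.05) {
  if (!is.character(category_label) || length(category_label) != 1) {
    stop("category_label must be a single string")
  }
  if (!is.finite(vis_gain) || vis_gain <= 0) stop("invalid profile: vis_gain must be > 0")
  if (!is.finite(nir_loss) || nir_loss <= 0) stop("invalid profile: nir_loss must be > 0")
  if (water_band_depth < 0) stop("water_band_depth must be >= 0")
  structure(list(category_label = category_label, vis_gain = vis_gain,
                 nir_loss = nir_loss, rededge_shift_nm = rededge_shift_nm,
                 water_band_depth = water_band_depth),
            class = "stress_profile")
}

#' Default three-level severity profiles
#'
#' Control / early / severe profiles whose visible gain increases and NIR
#' retention decreases monotonically with severity, with drying water bands
#' and a red-edge inflection that retreats toward longer wavelengths as the
#' edge flattens -- darkening the 700 nm shoulder relative to the red
#' trough, which is what drives the observed decline of all four vegetation
#' indices (including MCARI) along the severity gradient. Early stress is
#' dominated by water status (shallower 742/842 nm bands, slight NIR loss,
#' barely lifted visible) while severe stress adds pigment collapse (strong
#' visible lift), so the two stress signatures point in distinct spectral
#' directions rather than along one common gain axis -- the class geometry
#' stressed canopies actually show. These are the study conditions used by
#' the synthetic generator throughout the package.
#'
#' @return named list of [stress_profile()] objects in severity order.
#' @export
default_stress_profiles <- function() {
  list(
    control = stress_profile("control", 1.00, 1.00,  0, 0.050),
    early   = stress_profile("early",   1.05, 0.95,  4, 0.038),
    severe  = stress_profile("severe",  1.50, 0.85, 12, 0.025)
  )
}

#' Synthesise a canopy endmember reflectance spectrum
#'
#' Healthy-leaf model: a low visible baseline with a green reflectance bump
#' near 550 nm (chlorophyll/carotenoid absorption keeps the blue and the
#' ~670 nm red trough dark), a logistic red edge rising to a high NIR
#' plateau, and Gaussian water-absorption dips centred at 742 and 842 nm.
#' The profile's gains then scale the visible (<= 700 nm) and NIR
#' (>= 740 nm) windows, with a linear blend across the 700--740 nm red edge.
#'
#' @param profile a [stress_profile()].
#' @param grid a [wavelength_grid()].
#' @return numeric reflectance spectrum of length `grid$count`, in [0, 1].
#' @export
make_endmember <- function(profile, grid) {
  stopifnot(inherits(profile, "stress_profile"), inherits(grid, "wavelength_grid"))
  wl <- grid$wavelengths_nm
  vis <- 0.08 + 0.04 * exp(-(wl - 550)^2 / (2 * 18^2))
  r <- vis + (0.52 - 0.08) * plogis((wl - (718 + profile$rededge_shift_nm)) / 9)
  d <- profile$water_band_depth
  r <- r - d * (exp(-(wl - 742)^2 / (2 * 6^2)) +
                0.9 * exp(-(wl - 842)^2 / (2 * 10^2)))
  gain <- ifelse(wl <= 700, profile$vis_gain,
          ifelse(wl >= 740, profile$nir_loss,
                 profile$vis_gain +
                   (profile$nir_loss - profile$vis_gain) * (wl - 700) / 40))
  pmin(pmax(r * gain, 0), 1)
}

#' Default background (soil/bench) reflectance spectrum
#'
#' A dry-soil-like spectrum: moderately bright and nearly flat through the
#' visible and red edge, then rising steeply beyond ~820 nm. The NIR rise is
#' what makes the background, rather than the canopy, the brightest surface
#' in the 871.7 nm pseudo-colour channel, so canopy pixels render green
#' (hue ~1/3) and the published HSV thresholds isolate the plant.
#'
#' @param grid a [wavelength_grid()].
#' @return numeric reflectance spectrum of length `grid$count`.
#' @export
default_background_spectrum <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  spline(c(511, 680, 740, 791, 830, 872, 900),
         c(0.36, 0.40, 0.39, 0.38, 0.46, 0.64, 0.70),
         xout = grid$wavelengths_nm, method = "natural")$y
}
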