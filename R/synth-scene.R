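#' Synthetic scene specification
#'
#' Describes a synthetic greenhouse acquisition: image geometry, which
#' severity profile occupies which part of the canopy, the background
#' spectrum, per-pixel scatter distortion ranges, noise level and seed.
#'
#' @param height,width image size in pixels.
#' @param profiles list of [stress_profile()]s in severity order; pixels are
#'   labelled 1..K in this order.
#' @param layout `"bands"` splits the canopy into horizontal slabs, one per
#'   profile, most severe at the top (apical) end -- stress symptoms appear
#'   first in newly emerging apical leaves; `"uniform"` gives the whole
#'   canopy the first profile.
#' @param plant_region optional logical H x W matrix of canopy pixels; the
#'   default is a centred ellipse. Must be non-empty and strictly inside the
#'   image border.
#' @param background_spectrum optional length-B reflectance vector for the
#'   soil/bench background (resolved against the grid at render time).
#' @param scatter_slope,scatter_offset length-2 ranges of the per-pixel
#'   multiplicative slope and additive offset applied to reflectance before
#'   noise. Defaults are the identity (no scatter) so that calibration
#'   inverts the forward model exactly at zero noise.
#' @param noise_sd per-band Gaussian noise SD in reflectance units (>= 0).
#' @param white_dn,dark_dn digital numbers of the white and dark reference
#'   frames (12-bit scale).
#' @param seed integer RNG seed.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(height = 64, width = 64,
                       profiles = default_stress_profiles(),
                       layout = c("bands", "uniform"),
                       plant_region = NULL,
                       background_spectrum = NULL,
                       scatter_slope = c(1, 1), scatter_offset = c(0, 0),
                       noise_sd = 0.01,
                       white_dn = 3000, dark_dn = 100,
                       seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(height >= 8, width >= 8, length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "stress_profile")),
            length(scatter_slope) == 2, length(scatter_offset) == 2)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (white_dn <= dark_dn) {
    stop("degenerate references: white must exceed dark everywhere")
  }
  if (is.null(plant_region)) {
    rc <- expand.grid(r = seq_len(height), c = seq_len(width))
    plant_region <- matrix(
      ((rc$r - (height + 1) / 2) / (0.38 * height))^2 +
        ((rc$c - (width + 1) / 2) / (0.33 * width))^2 <= 1,
      nrow = height)
  }
  if (!is.matrix(plant_region) || !is.logical(plant_region) ||
      !identical(dim(plant_region), c(as.integer(height), as.integer(width)))) {
    stop("plant_region must be a logical height x width matrix")
  }
  if (!any(plant_region)) stop("plant_region must be non-empty")
  if (any(plant_region[c(1, height), ]) || any(plant_region[, c(1, width)])) {
    stop("plant_region must lie strictly inside the image")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 profiles = profiles, layout = layout,
                 plant_region = plant_region,
                 background_spectrum = background_spectrum,
                 scatter_slope = scatter_slope, scatter_offset = scatter_offset,
                 noise_sd = noise_sd, white_dn = white_dn, dark_dn = dark_dn,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Render a synthetic scene
#'
#' Builds the forward model `raw = dark + reflectance * (white - dark) +
#' noise * (white - dark)` pixel-wise, so that [calibrate_cube()] inverts it
#' up to noise. Canopy pixels carry the endmember spectrum of their severity
#' profile (optionally distorted by per-pixel scatter), background pixels
#' the background spectrum.
#'
#' @param spec a [scene_spec()].
#' @param grid a [wavelength_grid()].
#' @return list with elements `raw` ([raw_cube()]), `white`, `dark`
#'   ([reference_frame()]s), `mask` ([plant_mask()]) marking the true canopy,
#'   `labels` (integer H x W truth map, 0 = background, 1..K = severity
#'   rank), `categories` (severity names) and `reflectance` (the noise-free,
#'   scatter-free endmember cube, for ground-truth comparisons).
#' @export
render_scene <- function(spec, grid = default_grid()) {
  stopifnot(inherits(spec, "scene_spec"), inherits(grid, "wavelength_grid"))
  h <- spec$height; w <- spec$width; B <- grid$count
  ends <- lapply(spec$profiles, make_endmember, grid = grid)
  bg <- spec$background_spectrum %||% default_background_spectrum(grid)
  if (length(bg) != B) stop("background_spectrum length must equal band count")

  labels <- matrix(0L, h, w)
  fg_rows <- which(apply(spec$plant_region, 1, any))
  K <- length(ends)
  if (spec$layout == "uniform" || K == 1) {
    labels[spec$plant_region] <- 1L
  } else {
    # horizontal slabs, most severe profile at the top (apex)
    cuts <- quantile(fg_rows, probs = seq(0, 1, length.out = K + 1), type = 1)
    slab <- K + 1L - as.integer(cut(seq_len(h), breaks = unique(c(-Inf, cuts[-1])),
                                    labels = FALSE))
    slab[slab < 1L | slab > K] <- NA_integer_
    labels[spec$plant_region] <- slab[row(labels)[spec$plant_region]]
  }

  truth <- matrix(rep(bg, each = h * w), nrow = h * w)
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    if (length(idx)) truth[idx, ] <- matrix(rep(ends[[k]], each = length(idx)),
                                            nrow = length(idx))
  }

  refl <- with_seed(spec$seed, {
    n_px <- h * w
    slope <- runif(n_px, spec$scatter_slope[1], spec$scatter_slope[2])
    offset <- runif(n_px, spec$scatter_offset[1], spec$scatter_offset[2])
    r <- truth * slope + offset
    if (spec$noise_sd > 0) r <- r + matrix(rnorm(n_px * B, 0, spec$noise_sd), n_px)
    r
  })

  span <- spec$white_dn - spec$dark_dn
  raw <- pmax(spec$dark_dn + refl * span, 0)
  list(
    raw = raw_cube(matrix_to_cube_data(raw, h, w), grid,
                   meta = list(seed = spec$seed)),
    white = reference_frame(rep(spec$white_dn, B), grid, "white"),
    dark = reference_frame(rep(spec$dark_dn, B), grid, "dark"),
    mask = plant_mask(spec$plant_region),
    labels = labels,
    categories = vapply(spec$profiles, `[[`, "", "category_label"),
    reflectance = reflectance_cube(matrix_to_cube_data(truth, h, w), grid)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
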