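#' Radiometric calibration of a raw cube to reflectance
#'
#' Converts raw digital numbers to reflectance with the standard white/dark
#' two-point correction, `(raw - dark) / (white - dark)` element-wise, then
#' clips to `[0, clip_max]`. A Teflon white tile is ~99 % reflective, so
#' calibrated values slightly above 1 occur on specular pixels; the default
#' ceiling of 1.5 keeps them finite without hiding gross calibration errors.
#'
#' @param raw a [raw_cube()].
#' @param white,dark [reference_frame()]s (full frames or single spectra,
#'   broadcast over the image).
#' @param clip_max reflectance ceiling (default 1.5).
#' @return a [reflectance_cube()], finite everywhere.
#' @examples
#' g <- wavelength_grid(c(500, 600, 700))
#' rc <- raw_cube(array(5, c(2, 2, 3)), g)
#' w <- reference_frame(rep(9, 3), g, "white")
#' d <- reference_frame(rep(1, 3), g, "dark")
#' calibrate_cube(rc, w, d)$data[1, 1, 1]  # (5-1)/(9-1) = 0.5
#' @export
calibrate_cube <- function(raw, white, dark, clip_max = 1.5) {
  stopifnot(inherits(raw, "raw_cube"), inherits(white, "reference_frame"),
            inherits(dark, "reference_frame"), clip_max > 0)
  dims <- dim(raw$data)
  w <- reference_array(white, dims)
  d <- reference_array(dark, dims)
  denom <- w - d
  if (any(denom <= 0)) {
    bad <- which(denom <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "calibration error: white <= dark at pixel (%d, %d), band %d",
      bad[1], bad[2], bad[3]))
  }
  refl <- pmin(pmax((raw$data - d) / denom, 0), clip_max)
  reflectance_cube(refl, raw$grid)
}

#' Build a pseudo-colour composite from three bands
#'
#' Assembles an H x W x 3 false-colour image from the nearest bands to the
#' requested wavelengths, min-max rescaling each channel to [0, 1]
#' independently. Defaults are the three high-contrast bands used for
#' canopy/background separation (679.7, 790.9, 871.7 nm). A constant plane
#' rescales to 0.
#'
#' @param cube a [reflectance_cube()].
#' @param wl_r,wl_g,wl_b channel wavelengths in nm.
#' @param enhance if TRUE (default), each channel plane passes through a
#'   3 x 3 median filter (edge-replicated) before rescaling -- the composite
#'   enhancement step that suppresses per-pixel sensor noise ahead of HSV
#'   thresholding while preserving the canopy boundary.
#' @return H x W x 3 array in [0, 1].
#' @export
build_pseudocolor <- function(cube, wl_r = 679.7, wl_g = 790.9, wl_b = 871.7,
                              enhance = TRUE) {
  stopifnot(inherits(cube, "reflectance_cube"))
  wls <- c(wl_r, wl_g, wl_b)
  if (anyDuplicated(wls)) {
    message("duplicate pseudo-colour wavelengths: composite is degenerate")
  }
  idx <- vapply(wls, function(t) nearest_band(cube$grid, t), 1L)
  rescale01 <- function(p) {
    rng <- range(p)
    if (rng[2] - rng[1] <= 0) return(p * 0)
    (p - rng[1]) / (rng[2] - rng[1])
  }
  d <- dim(cube$data)
  out <- array(0, c(d[1], d[2], 3))
  for (ch in 1:3) {
    plane <- cube$data[, , idx[ch]]
    if (enhance) plane <- median_smooth3(plane)
    out[, , ch] <- rescale01(plane)
  }
  out
}

# 3x3 median filter with edge replication (edge-preserving denoising)
median_smooth3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- m[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  stack <- vapply(0:8, function(k) {
    pad[(k %% 3) + seq_len(h), (k %/% 3) + seq_len(w)]
  }, matrix(0, h, w))
  apply(stack, c(1, 2), stats::median)
}

#' Segment the plant canopy by HSV thresholds
#'
#' Converts the pseudo-colour composite to HSV (each channel on [0, 1]) and
#' keeps pixels falling inside all three closed ranges; connected foreground
#' components smaller than `min_object_px` (4-connectivity) are then
#' removed. Defaults are the empirically optimised thresholds for the
#' greenhouse potato/sweet-potato composites: hue 0.223-0.412, saturation
#' 0.762-1.0, value 0.001-1.0.
#'
#' @param composite H x W x 3 array in [0, 1] (see [build_pseudocolor()]).
#' @param h_range,s_range,v_range closed threshold intervals on [0, 1].
#' @param min_object_px smallest connected component kept (default 64).
#' @return a [plant_mask()]; an empty result warns rather than errors so
#'   pipelines can report segmentation failure.
#' @export
segment_plant <- function(composite,
                          h_range = c(0.223, 0.412),
                          s_range = c(0.762, 1.0),
                          v_range = c(0.001, 1.0),
                          min_object_px = 64) {
  stopifnot(length(dim(composite)) == 3, dim(composite)[3] == 3,
            min(composite) >= 0, max(composite) <= 1)
  for (rg in list(h_range, s_range, v_range)) {
    stopifnot(length(rg) == 2, rg[1] <= rg[2], rg[1] >= 0, rg[2] <= 1)
  }
  h <- dim(composite)[1]; w <- dim(composite)[2]
  px <- matrix(composite, h * w, 3)
  hsv <- t(rgb2hsv(t(px), maxColorValue = 1))
  keep <- hsv[, 1] >= h_range[1] & hsv[, 1] <= h_range[2] &
          hsv[, 2] >= s_range[1] & hsv[, 2] <= s_range[2] &
          hsv[, 3] >= v_range[1] & hsv[, 3] <= v_range[2]
  m <- matrix(keep, h, w)
  if (min_object_px > 1 && any(m)) {
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0])
    m <- m & matrix(sizes[pmax(lab, 1)] >= min_object_px & lab > 0, h, w)
  }
  if (!any(m)) warning("segmentation produced an empty mask")
  plant_mask(m)
}

# 4-connectivity connected-component labelling (two-pass union-find)
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (cc in seq_len(w)) for (rr in seq_len(h)) {
    if (!mask[rr, cc]) next
    up <- if (rr > 1) lab[rr - 1, cc] else 0L
    left <- if (cc > 1) lab[rr, cc - 1] else 0L
    if (up == 0L && left == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[rr, cc] <- nxt
    } else if (up != 0L && left != 0L) {
      ru <- find(up); rl <- find(left)
      lab[rr, cc] <- ru
      if (ru != rl) parent[rl] <- ru
    } else {
      lab[rr, cc] <- max(up, left)
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, 1L)
  compact <- match(roots, unique(roots))
  lab[lab > 0L] <- compact[lab[lab > 0L]]
  lab
}

#' Zero out the background of a cube
#'
#' Sets every band of non-canopy pixels to 0 and attaches the mask to the
#' cube; canopy pixels are untouched.
#'
#' @param cube a [reflectance_cube()].
#' @param mask a [plant_mask()] of matching size.
#' @return masked [reflectance_cube()].
#' @export
apply_mask <- function(cube, mask) {
  stopifnot(inherits(cube, "reflectance_cube"), inherits(mask, "plant_mask"))
  if (!identical(dim(mask$data), dim(cube$data)[1:2])) {
    stop("mask dimensions do not match cube")
  }
  d <- cube$data
  bg <- which(!mask$data)
  if (length(bg)) {
    m <- cube_to_matrix(cube)
    m[bg, ] <- 0
    d <- matrix_to_cube_data(m, nrow(mask$data), ncol(mask$data))
  }
  reflectance_cube(d, cube$grid, mask = mask, provenance = cube$provenance)
}

#' Extract mean ROI spectra from a masked cube
#'
#' Places `n_rois` non-overlapping square regions of interest of
#' `roi_size_px` pixels entirely inside the canopy mask (seeded random
#' placement) and returns the mean spectrum of each as one row of a
#' [spectra_table()]. Three replicates per plant is the conventional
#' sampling density.
#'
#' @param cube a masked [reflectance_cube()] (see [apply_mask()]).
#' @param n_rois number of ROIs (default 3).
#' @param roi_size_px pixels per ROI; must be a perfect square (default 25,
#'   i.e. 5 x 5).
#' @param seed RNG seed for placement.
#' @param label category label attached to the extracted rows.
#' @return a [spectra_table()] with `n_rois` rows; the pixel indices of each
#'   ROI are attached as attribute `roi_pixels`.
#' @export
extract_roi_spectra <- function(cube, n_rois = 3, roi_size_px = 25,
                                seed = 1L, label = "unknown") {
  stopifnot(inherits(cube, "reflectance_cube"), n_rois >= 1)
  if (is.null(cube$mask)) stop("cube must be masked before ROI extraction")
  side <- as.integer(round(sqrt(roi_size_px)))
  if (side * side != roi_size_px) stop("roi_size_px must be a perfect square")
  fg <- cube$mask$data
  if (cube$mask$n_foreground < roi_size_px) {
    stop("foreground smaller than one ROI")
  }
  h <- nrow(fg); w <- ncol(fg)
  # summed-area table to find all top-left corners whose side x side window
  # is fully foreground
  sat <- apply(apply(fg, 2, cumsum), 1, cumsum)  # sat[c, r] after transpose
  win_sum <- function(r, c) {
    r2 <- r + side - 1L; c2 <- c + side - 1L
    sat[c2, r2] - (if (c > 1) sat[c - 1, r2] else 0) -
      (if (r > 1) sat[c2, r - 1] else 0) +
      (if (r > 1 && c > 1) sat[c - 1, r - 1] else 0)
  }
  cand <- expand.grid(r = seq_len(h - side + 1L), c = seq_len(w - side + 1L))
  full <- mapply(win_sum, cand$r, cand$c) == side * side
  cand <- cand[full, , drop = FALSE]
  rois <- with_seed(seed, {
    picked <- list()
    while (length(picked) < n_rois && nrow(cand) > 0) {
      i <- sample.int(nrow(cand), 1)
      p <- cand[i, ]
      picked[[length(picked) + 1]] <- p
      overlap <- abs(cand$r - p$r) < side & abs(cand$c - p$c) < side
      cand <- cand[!overlap, , drop = FALSE]
    }
    picked
  })
  if (length(rois) < n_rois) {
    stop(sprintf("could only place %d of %d non-overlapping ROIs", length(rois), n_rois))
  }
  m <- cube_to_matrix(cube)
  pixel_sets <- lapply(rois, function(p) {
    as.vector(outer(p$r + 0:(side - 1L), (p$c + 0:(side - 1L) - 1L) * h, `+`))
  })
  X <- do.call(rbind, lapply(pixel_sets, function(px) colMeans(m[px, , drop = FALSE])))
  out <- spectra_table(X, rep(label, length(rois)), cube$grid,
                       provenance = cube$provenance)
  attr(out, "roi_pixels") <- pixel_sets
  out
}
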