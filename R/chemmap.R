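#' Pixel-wise chemical severity map from a PLS-DA model
#'
#' Multiplies each foreground pixel's (preprocessed) spectrum at the
#' model's selected bands by the PLS-DA beta coefficients, giving an
#' H x W x C cube of continuous category scores — the "chemical image" that
#' localises stress expression within the canopy. The cube's preprocessing
#' provenance must match the model's stored preprocessing exactly;
#' mismatches are a hard error because a map built on differently
#' preprocessed spectra is silently invalid.
#'
#' @param cube a masked, preprocessed [reflectance_cube()].
#' @param model a [fit_plsda()] model; its `bands` field (indices into the
#'   cube grid) selects the wavelengths, NULL meaning all; its `preprocess`
#'   field (character provenance) is checked against the cube.
#' @return object of class `chemical_map`: `score_map` (H x W x C,
#'   background NA), `categories`, `threshold`, `mask`.
#' @export
chemical_map <- function(cube, model) {
  stopifnot(inherits(cube, "reflectance_cube"), inherits(model, "plsda_model"))
  if (is.null(cube$mask)) stop("cube must be masked before chemical mapping")
  if (!identical(as.character(model$preprocess %||% character()),
                 as.character(cube$provenance))) {
    stop(sprintf(
      "preprocessing mismatch: model expects [%s], cube carries [%s]",
      paste(model$preprocess, collapse = " -> "),
      paste(cube$provenance, collapse = " -> ")))
  }
  bands <- model$bands %||% seq_len(cube$grid$count)
  if (length(bands) != nrow(model$beta)) {
    stop("model band list does not match its beta coefficients")
  }
  m <- cube_to_matrix(cube)[, bands, drop = FALSE]
  fg <- which(cube$mask$data)
  pred <- predict_plsda(model, m[fg, , drop = FALSE])
  d <- dim(cube$data)
  score <- array(NA_real_, c(d[1], d[2], length(model$categories)))
  for (k in seq_along(model$categories)) {
    plane <- matrix(NA_real_, d[1], d[2])
    plane[fg] <- pred$scores[, k]
    score[, , k] <- plane
  }
  structure(list(score_map = score, categories = model$categories,
                 threshold = model$threshold, mask = cube$mask),
            class = "chemical_map")
}

#' Threshold a chemical map into category labels
#'
#' Foreground pixels take the arg-max category when the winning score
#' exceeds `threshold` (the 0.5 class-boundary rule), and the label
#' `"uncertain"` (code 0) otherwise; background pixels carry NA.
#'
#' @param map a [chemical_map()].
#' @param threshold decision value (default: the map's stored threshold).
#' @return list with `label_map` (integer H x W: NA background, 0
#'   uncertain, 1..C category index) and `fractions` (named per-category +
#'   uncertain pixel fractions over the foreground, summing to 1).
#' @export
classify_map <- function(map, threshold = NULL) {
  stopifnot(inherits(map, "chemical_map"))
  threshold <- threshold %||% map$threshold
  d <- dim(map$score_map)
  fg <- which(map$mask$data)
  scores <- matrix(map$score_map, d[1] * d[2], d[3])[fg, , drop = FALSE]
  win <- max.col(scores, ties.method = "first")
  lab <- ifelse(scores[cbind(seq_along(win), win)] > threshold, win, 0L)
  label_map <- matrix(NA_integer_, d[1], d[2])
  label_map[fg] <- lab
  counts <- tabulate(lab + 1L, nbins = d[3] + 1L)
  fractions <- stats::setNames(counts / length(fg),
                               c("uncertain", map$categories))
  list(label_map = label_map, fractions = fractions)
}

#' Render a chemical map to a colour image
#'
#' Writes an 8-bit PNG: the arg-max severity rank is rescaled onto a
#' blue -> green -> yellow gradient (blue = healthy, yellow/green =
#' severe), uncertain pixels neutral grey, background black. Colour
#' scaling is recorded in a sidecar JSON so renders are reproducible.
#'
#' @param map a [chemical_map()].
#' @param path output PNG path (sidecar written to `<path>.json`).
#' @param score_range score range mapped onto the gradient (default
#'   c(0, 1)).
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path, score_range = c(0, 1)) {
  stopifnot(inherits(map, "chemical_map"))
  cls <- classify_map(map)
  d <- dim(map$score_map)
  # severity scalar: rank of the winning category, scaled to [0, 1]
  sev_rank <- (seq_along(map$categories) - 1) / max(1, length(map$categories) - 1)
  img <- array(0, c(d[1], d[2], 3))
  ramp <- grDevices::colorRamp(c("#2040c0", "#20a060", "#e0e020"))
  fg <- which(map$mask$data & !is.na(cls$label_map) & cls$label_map > 0)
  unc <- which(map$mask$data & cls$label_map == 0)
  if (length(fg)) {
    s01 <- pmin(pmax((sev_rank[cls$label_map[fg]] - score_range[1]) /
                       diff(score_range), 0), 1)
    cols <- ramp(s01) / 255
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[fg] <- cols[, ch]; img[, , ch] <- plane
    }
  }
  if (length(unc)) {
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[unc] <- 0.5; img[, , ch] <- plane
    }
  }
  ok <- tryCatch({ png::writePNG(img, path); TRUE },
                 error = function(e) stop("cannot write image: ", conditionMessage(e)))
  jsonlite::write_json(
    list(colormap = "blue-green-yellow", score_range = score_range,
         categories = map$categories, threshold = map$threshold,
         uncertain_grey = 0.5, background = "black"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
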