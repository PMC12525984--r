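#' Hyperspectral cube containers
#'
#' Light S3 containers around an H x W x B array plus its wavelength grid.
#' `raw_cube` holds digital numbers straight off the sensor (12-bit scale),
#' `reflectance_cube` holds calibrated reflectance (optionally masked),
#' `reference_frame` holds a white or dark reference (a full frame or a
#' single spectrum broadcast over the image).
#'
#' @param data numeric H x W x B array (or length-B vector for a reference).
#' @param grid a [wavelength_grid()].
#' @param meta free-form acquisition metadata list.
#' @return the corresponding S3 object.
#' @name cube-containers
NULL

#' @rdname cube-containers
#' @export
raw_cube <- function(data, grid, meta = list()) {
  stopifnot(inherits(grid, "wavelength_grid"))
  data <- check_cube_array(data, grid)
  if (any(data < 0)) stop("raw digital numbers must be >= 0")
  structure(list(data = data, grid = grid, meta = meta), class = "raw_cube")
}

#' @rdname cube-containers
#' @param mask optional [plant_mask()] attached to the cube.
#' @param provenance character vector of preprocessing steps applied so far.
#' @export
reflectance_cube <- function(data, grid, mask = NULL, provenance = character()) {
  stopifnot(inherits(grid, "wavelength_grid"))
  data <- check_cube_array(data, grid)
  if (any(!is.finite(data))) stop("reflectance cube must be finite everywhere")
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "plant_mask"))
    if (!identical(dim(mask$data), dim(data)[1:2])) {
      stop("mask dimensions do not match cube")
    }
  }
  structure(list(data = data, grid = grid, mask = mask, provenance = provenance),
            class = "reflectance_cube")
}

#' @rdname cube-containers
#' @param role `"white"` or `"dark"`.
#' @export
reference_frame <- function(data, grid, role = c("white", "dark")) {
  role <- match.arg(role)
  stopifnot(inherits(grid, "wavelength_grid"))
  if (is.null(dim(data))) {
    if (length(data) != grid$count) stop("reference spectrum length must equal band count")
    data <- as.numeric(data)
  } else {
    data <- check_cube_array(data, grid)
  }
  structure(list(data = data, grid = grid, role = role), class = "reference_frame")
}

#' Binary plant mask
#'
#' @param data logical H x W matrix, TRUE for canopy pixels.
#' @return object of class `plant_mask` with fields `data` and
#'   `n_foreground`.
#' @export
plant_mask <- function(data) {
  if (!is.matrix(data) || !is.logical(data)) stop("mask must be a logical matrix")
  structure(list(data = data, n_foreground = sum(data)), class = "plant_mask")
}

#' @export
print.plant_mask <- function(x, ...) {
  cat(sprintf("<plant_mask> %dx%d, %d foreground pixels\n",
              nrow(x$data), ncol(x$data), x$n_foreground))
  invisible(x)
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<reflectance_cube> %dx%d pixels, %d bands (%.1f-%.1f nm)%s\n",
              d[1], d[2], d[3], x$grid$wavelengths_nm[1],
              x$grid$wavelengths_nm[x$grid$count],
              if (!is.null(x$mask)) sprintf(", masked (%d fg px)", x$mask$n_foreground) else ""))
  if (length(x$provenance)) cat("  preprocessing:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

check_cube_array <- function(data, grid) {
  if (length(dim(data)) != 3) stop("cube data must be a 3-d array (H x W x bands)")
  if (dim(data)[3] != grid$count) {
    stop(sprintf("cube has %d bands but grid has %d", dim(data)[3], grid$count))
  }
  data
}

# broadcast a reference frame to H x W x B
reference_array <- function(ref, dims) {
  if (is.null(dim(ref$data))) {
    aperm(array(ref$data, dim = c(dims[3], dims[1], dims[2])), c(2, 3, 1))
  } else {
    if (!identical(dim(ref$data), dims)) stop("reference frame dimensions do not match cube")
    ref$data
  }
}

# flatten cube to (H*W) x B matrix of pixel spectra (row-major within columns)
cube_to_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}

matrix_to_cube_data <- function(m, h, w) {
  array(m, dim = c(h, w, ncol(m)))
}
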