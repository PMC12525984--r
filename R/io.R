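#' Write / read a cube as ENVI header + band-sequential raw
#'
#' Minimal ENVI interchange: a text `.hdr` describing dimensions,
#' interleave, data type and wavelengths, beside a raw binary file of
#' 32-bit little-endian floats in band-sequential (BSQ) order.
#'
#' @param cube a [reflectance_cube()] or [raw_cube()].
#' @param path path of the raw file; the header goes to `<path>.hdr`.
#' @return `write_envi` returns `path` invisibly; `read_envi` returns a
#'   [reflectance_cube()].
#' @export
write_envi <- function(cube, path) {
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {canopyspec export}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }",
            paste(sprintf("%.4f", cube$grid$wavelengths_nm), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: band-major, then row-major within a band plane
  for (b in seq_len(d[3])) {
    writeBin(as.numeric(t(cube$data[, , b])), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_envi
#' @export
read_envi <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  grab <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(ln)) stop("missing ENVI header field: ", key)
    sub(".*= *", "", ln[1])
  }
  samples <- as.integer(grab("samples"))
  lines_n <- as.integer(grab("lines"))
  bands <- as.integer(grab("bands"))
  if (grab("interleave") != "bsq") stop("only BSQ interleave supported")
  if (as.integer(grab("data type")) != 4) stop("only float32 (type 4) supported")
  wl_txt <- sub(".*\\{", "", paste(hdr[grep("wavelength *=", hdr)[1]:length(hdr)],
                                   collapse = " "))
  wl <- as.numeric(strsplit(gsub("[}{]", "", wl_txt), ",")[[1]])
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = samples * lines_n * bands, size = 4,
                  endian = "little")
  data <- array(NA_real_, c(lines_n, samples, bands))
  for (b in seq_len(bands)) {
    plane <- vals[((b - 1) * samples * lines_n + 1):(b * samples * lines_n)]
    data[, , b] <- matrix(plane, lines_n, samples, byrow = TRUE)
  }
  reflectance_cube(data, wavelength_grid(wl[seq_len(bands)]))
}

#' Write / read a cube as a multi-page TIFF
#'
#' One 32-bit float page per band; wavelengths go to a sidecar JSON
#' (`<path>.json`) because baseline TIFF has no spectral axis.
#'
#' @param cube a [reflectance_cube()].
#' @param path TIFF path.
#' @return `write_cube_tiff` returns `path` invisibly; `read_cube_tiff`
#'   returns a [reflectance_cube()].
#' @export
write_cube_tiff <- function(cube, path) {
  d <- dim(cube$data)
  pages <- lapply(seq_len(d[3]), function(b) cube$data[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  jsonlite::write_json(list(wavelengths_nm = cube$grid$wavelengths_nm),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_cube_tiff
#' @export
read_cube_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  reflectance_cube(data, wavelength_grid(meta$wavelengths_nm))
}

#' Write a plant mask as an 8-bit PNG
#'
#' @param mask a [plant_mask()].
#' @param path PNG path (foreground white, background black).
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "plant_mask"))
  png::writePNG(mask$data * 1, path)
  invisible(path)
}
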