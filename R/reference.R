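#' Published reference tables from the greenhouse stress experiments
#'
#' Accessors for the small plain-text fixtures shipped with the package:
#' the reported calibration/validation/test partition sizes and
#' SPA-selected band lists per cultivar x stress dataset, the reported
#' classifier performance metrics, and the acquisition-design summary
#' (greenhouses x rows x images per week x weeks). These support
#' regression-style arithmetic checks; no spectral data is included
#' (the greenhouse cubes are available only on request from the original
#' experimenters).
#'
#' @return `reference_partitions()`: data frame with `dataset`, `n_bands`,
#'   `calibration`, `validation`, `test`; `reference_bands()`: named list
#'   of selected wavelength vectors (nm); `reference_performance()`: data
#'   frame of reported accuracy/precision/recall/F1/AUC per dataset x model;
#'   `reference_design()`: data frame of the acquisition design.
#' @name reference-tables
NULL

#' @rdname reference-tables
#' @export
reference_partitions <- function() {
  read.csv(system.file("extdata", "reference_partitions.csv",
                       package = "canopyspec"))
}

#' @rdname reference-tables
#' @export
reference_bands <- function() {
  jsonlite::read_json(system.file("extdata", "reference_bands.json",
                                  package = "canopyspec"),
                      simplifyVector = TRUE)
}

#' @rdname reference-tables
#' @export
reference_performance <- function() {
  read.csv(system.file("extdata", "reference_performance.csv",
                       package = "canopyspec"))
}

#' @rdname reference-tables
#' @export
reference_design <- function() {
  read.csv(system.file("extdata", "reference_design.csv",
                       package = "canopyspec"))
}

#' Total images implied by an acquisition design
#'
#' `greenhouses x rows x images_per_week x weeks` -- the arithmetic behind
#' the design summary's HSI totals (e.g. 2 x 6 x 30 x 5 = 1800 for the
#' potato drought campaign).
#'
#' @param greenhouses,rows,images_per_week,weeks design factors.
#' @return integer total image count.
#' @export
design_total_images <- function(greenhouses, rows, images_per_week, weeks) {
  as.integer(greenhouses * rows * images_per_week * weeks)
}
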