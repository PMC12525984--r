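#' Largest-remainder allocation of n samples to fractions
#'
#' Floors `n * fractions`, then hands the remaining units to the sets with
#' the largest fractional remainders; exact ties go to the earlier set in
#' the given order (calibration before validation before test).
#'
#' @param n total count.
#' @param fractions named fractions summing to 1 (default 60/20/20
#'   cal/val/test).
#' @return named integer vector summing to `n`.
#' @examples
#' largest_remainder(3450)  # 2070 690 690
#' largest_remainder(6558)  # 3935 1312 1311
#' @export
largest_remainder <- function(n, fractions = c(cal = 0.6, val = 0.2, test = 0.2)) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, n >= 0)
  exact <- n * fractions
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    # order(-remainder) is stable, so ties keep the fractions' given order
    extra <- order(-(exact - base))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Stratified calibration/validation/test split
#'
#' Allocates each category's rows 60/20/20 (configurable) with
#' largest-remainder rounding and a seeded shuffle; the three sets are
#' disjoint and exhaustive, and the test set plays no role in any model
#' fitting or selection.
#'
#' @param tbl a [spectra_table()].
#' @param fractions named split fractions (default cal 0.6, val 0.2,
#'   test 0.2).
#' @param seed RNG seed for the within-category shuffle.
#' @return the table with its `split` column assigned.
#' @export
stratified_split <- function(tbl, fractions = c(cal = 0.6, val = 0.2, test = 0.2),
                             seed = 1L) {
  stopifnot(inherits(tbl, "spectra_table"))
  counts <- table(tbl$labels)
  if (any(counts < 5)) {
    stop(sprintf("categories too small for a stratified split: %s",
                 paste(names(counts)[counts < 5], collapse = ", ")))
  }
  split <- rep(NA_character_, nrow(tbl$X))
  with_seed(seed, {
    for (cat in names(counts)) {
      idx <- sample(which(tbl$labels == cat))
      alloc <- largest_remainder(length(idx), fractions)
      split[idx] <- rep(names(alloc), alloc)
    }
  })
  spectra_table(tbl$X, tbl$labels, tbl$grid, split = split,
                provenance = tbl$provenance)
}
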