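#' Synthetic severity-recovery experiment
#'
#' The package's stand-in for the greenhouse benchmark: for each seed it
#' draws a balanced three-severity spectra table under the default study
#' conditions (scatter + noise), splits it 60/20/20, preprocesses, fits the
#' three classifiers (PLS-DA with 10 latent variables; shrinkage LDA and
#' RBF-SVM, both tuned by stratified 5-fold cross-validation on the
#' calibration set), optionally runs SPA band selection scored on the
#' validation set and refits a reduced PLS-DA, and scores everything on the
#' untouched test set.
#'
#' @param seeds integer vector of seeds, one experiment per seed.
#' @param n_per_category spectra per severity category (default 200, i.e.
#'   N = 600).
#' @param grid a [wavelength_grid()] (default: the 194-band working grid).
#' @param preprocessing preprocessing name (default `"snv"`).
#' @param spa run SPA band selection and a reduced model (default TRUE).
#' @param spa_k length-2 subset size range searched (default c(21, 32), the
#'   published selection range).
#' @param spa_starts number of chain starts, spread evenly over the grid.
#' @return data frame with one row per seed: test accuracies of each
#'   classifier (`acc_plsda`, `acc_lda`, `acc_svm`, and `acc_spa_plsda` if
#'   requested), `spa_k` (subset size), and `extreme_confusions` (test
#'   samples confused between control and severe by any classifier).
#' @export
severity_recovery_experiment <- function(seeds = 1:10, n_per_category = 200,
                                         grid = default_grid(),
                                         preprocessing = "snv",
                                         spa = TRUE, spa_k = c(21, 32),
                                         spa_starts = 8) {
  rows <- lapply(seeds, function(seed) {
    tbl <- sample_spectra_table(
      c(control = n_per_category, early = n_per_category,
        severe = n_per_category), grid = grid, seed = seed)
    tbl <- stratified_split(tbl, seed = seed)
    S <- preprocess_table(tbl, preprocess_spec(preprocessing))$table
    pick <- function(s) list(X = S$X[S$split == s, , drop = FALSE],
                             y = S$labels[S$split == s])
    cal <- pick("cal"); val <- pick("val"); test <- pick("test")

    plsda <- fit_plsda(cal$X, cal$y, n_lv = 10)
    lda <- fit_lda(cal$X, cal$y, seed = seed)
    svmm <- fit_svm_ovr(cal$X, cal$y, seed = seed)
    preds <- list(
      plsda = predict_plsda(plsda, test$X)$category,
      lda = predict_lda(lda, test$X)$category,
      svm = predict_svm_ovr(svmm, test$X)$category)

    out <- data.frame(seed = seed,
                      acc_plsda = mean(preds$plsda == test$y),
                      acc_lda = mean(preds$lda == test$y),
                      acc_svm = mean(preds$svm == test$y))
    if (spa) {
      starts <- unique(round(seq(1, grid$count, length.out = spa_starts)))
      sel <- spa_select(cal$X, cal$y, val$X, val$y,
                        k_min = spa_k[1], k_max = spa_k[2], starts = starts)
      reduced <- fit_plsda(cal$X[, sel$selected_indices, drop = FALSE],
                           cal$y, n_lv = min(10, sel$k))
      preds$spa_plsda <- predict_plsda(
        reduced, test$X[, sel$selected_indices, drop = FALSE])$category
      out$acc_spa_plsda <- mean(preds$spa_plsda == test$y)
      out$spa_k <- sel$k
    }
    out$extreme_confusions <- sum(vapply(preds, function(p) {
      sum((test$y == "control" & p == "severe") |
            (test$y == "severe" & p == "control"))
    }, 1))
    out
  })
  do.call(rbind, rows)
}
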