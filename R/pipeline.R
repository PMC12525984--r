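#' Default pipeline configuration
#'
#' The configuration drives every stage of [run_pipeline()]: synthetic
#' study design (per-category spectra counts, scene size, seed), HSV
#' segmentation thresholds, spectral preprocessing, SPA search range,
#' model hyperparameter grids and the split fractions. Values here are the
#' package's scaled-down defaults for a desk-size run; any field can be
#' overridden via the `config` argument or a YAML file.
#'
#' @return nested list of configuration values.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    grid = list(count = 194),
    synth = list(counts = c(control = 200, early = 200, severe = 200),
                 noise_sd = 0.01,
                 scatter_slope = c(0.8, 1.2), scatter_offset = c(-0.05, 0.05),
                 scene = list(height = 48, width = 48, noise_sd = 0)),
    hsv = list(h = c(0.223, 0.412), s = c(0.762, 1.0), v = c(0.001, 1.0),
               min_object_px = 64),
    preprocessing = "snv",
    split = list(fractions = c(cal = 0.6, val = 0.2, test = 0.2)),
    spa = list(enabled = TRUE, k_min = 6, k_max = 12, n_starts = 8),
    models = list(plsda = list(n_lv = 10),
                  lda = list(lambda_grid = c(0, 0.01, 0.1, 0.3, 0.5), folds = 5),
                  svm = list(cost_grid = c(0.1, 1, 10, 100), folds = 5))
  )
}

#' Run the full synthetic-to-map analysis pipeline
#'
#' Executes the standard workflow order: simulate -> calibrate -> segment ->
#' preprocess -> indices -> band selection -> train -> evaluate -> chemical
#' map, writing artifacts (summary CSV shaped like the published
#' performance tables, partition report, selection JSON, rendered map) into
#' `out_dir`. Every output carries the configuration hash; a failing stage
#' halts with a stage-named error, retaining the artifacts written so far.
#'
#' @param config a config list (see [default_run_config()]), a YAML file
#'   path, or NULL for the defaults; partial lists are completed with
#'   defaults.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the summary data frame, partition report,
#'   fitted models, selection result and map, plus `config_hash`.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("canopyspec_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_run_config(), config %||% list())
  cfg$synth$counts <- unlist(cfg$synth$counts)
  hash <- rlang::hash(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(config = cfg, config_hash = hash),
                       file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  grid <- wavelength_grid(seq(511, 900, length.out = cfg$grid$count))

  tbl <- stage("simulate", sample_spectra_table(
    cfg$synth$counts, grid = grid, seed = cfg$seed,
    scatter_slope = cfg$synth$scatter_slope,
    scatter_offset = cfg$synth$scatter_offset,
    noise_sd = cfg$synth$noise_sd))
  scene <- stage("simulate", render_scene(scene_spec(
    height = cfg$synth$scene$height, width = cfg$synth$scene$width,
    noise_sd = cfg$synth$scene$noise_sd, seed = cfg$seed + 1L), grid))

  refl <- stage("calibrate", calibrate_cube(scene$raw, scene$white, scene$dark))
  mask <- stage("segment", segment_plant(
    build_pseudocolor(refl), cfg$hsv$h, cfg$hsv$s, cfg$hsv$v,
    min_object_px = cfg$hsv$min_object_px))
  masked <- stage("segment", apply_mask(refl, mask))

  tbl <- stage("split", stratified_split(tbl, unlist(cfg$split$fractions),
                                         seed = cfg$seed))
  partitions <- as.data.frame.matrix(table(tbl$labels, tbl$split))
  partitions <- cbind(category = rownames(partitions), partitions,
                      config_hash = hash)
  write.csv(partitions, file.path(out_dir, "partitions.csv"), row.names = FALSE)

  idx <- stage("indices", compute_indices(tbl))
  duncan <- stage("indices", lapply(
    stats::setNames(nm = c("NDVI", "RDVI", "GNDVI", "MCARI")),
    function(v) anova_duncan(idx[[v]], idx$treatment)))
  letters_tbl <- do.call(rbind, lapply(names(duncan), function(v) {
    cbind(index = v, duncan[[v]]$groups, F = duncan[[v]]$F,
          p_value = duncan[[v]]$p_value, config_hash = hash)
  }))
  write.csv(letters_tbl, file.path(out_dir, "index_letters.csv"),
            row.names = FALSE)

  pp <- stage("preprocess", preprocess_table(
    tbl, preprocess_spec(cfg$preprocessing)))
  ptbl <- pp$table; pspec <- pp$spec
  sets <- lapply(c(cal = "cal", val = "val", test = "test"), function(s) {
    list(X = ptbl$X[ptbl$split == s, , drop = FALSE],
         y = ptbl$labels[ptbl$split == s])
  })

  selection <- NULL
  if (isTRUE(cfg$spa$enabled)) {
    starts <- unique(round(seq(1, grid$count, length.out = cfg$spa$n_starts)))
    selection <- stage("select-bands", spa_select(
      sets$cal$X, sets$cal$y, sets$val$X, sets$val$y,
      k_min = cfg$spa$k_min, k_max = cfg$spa$k_max,
      starts = starts, grid = grid))
    jsonlite::write_json(
      list(indices = selection$selected_indices,
           wavelengths_nm = selection$selected_wavelengths_nm,
           k = selection$k, score = selection$score,
           criterion = selection$criterion_name, config_hash = hash),
      file.path(out_dir, "selected_bands.json"), auto_unbox = TRUE, digits = NA)
  }

  models <- stage("train", list(
    plsda = fit_plsda(sets$cal$X, sets$cal$y, n_lv = cfg$models$plsda$n_lv),
    lda = fit_lda(sets$cal$X, sets$cal$y,
                  lambda_grid = cfg$models$lda$lambda_grid,
                  folds = cfg$models$lda$folds, seed = cfg$seed),
    svm = fit_svm_ovr(sets$cal$X, sets$cal$y,
                      cost_grid = cfg$models$svm$cost_grid,
                      folds = cfg$models$svm$folds, seed = cfg$seed)))
  if (!is.null(selection)) {
    models$spa_plsda <- fit_plsda(
      sets$cal$X[, selection$selected_indices, drop = FALSE], sets$cal$y,
      n_lv = min(cfg$models$plsda$n_lv, selection$k))
    models$spa_plsda$bands <- selection$selected_indices
  }

  summary_df <- stage("evaluate", {
    rows <- list()
    for (mn in names(models)) {
      bands <- models[[mn]]$bands
      for (sn in names(sets)) {
        X <- sets[[sn]]$X
        if (!is.null(bands)) X <- X[, bands, drop = FALSE]
        pred <- switch(class(models[[mn]])[1],
          plsda_model = { p <- predict_plsda(models[[mn]], X)
                          list(cat = p$category, sc = p$scores) },
          lda_model = { p <- predict_lda(models[[mn]], X)
                        list(cat = p$category, sc = p$delta) },
          svm_ovr_model = { p <- predict_svm_ovr(models[[mn]], X)
                            list(cat = p$category, sc = p$decision) })
        ev <- evaluate(sets[[sn]]$y, pred$cat, pred$sc, set_name = sn)
        rows[[length(rows) + 1]] <- data.frame(
          model = mn,
          bands = if (is.null(bands)) "full spectrum" else as.character(length(bands)),
          preprocessing = cfg$preprocessing, set = sn,
          accuracy_pct = round(100 * ev$accuracy, 2),
          precision = round(ev$precision, 3), recall = round(ev$recall, 3),
          f1 = round(ev$f1, 3), auc = round(ev$auc, 3),
          config_hash = hash)
      }
    }
    do.call(rbind, rows)
  })
  write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)

  map <- stage("map", {
    map_model <- models$spa_plsda %||% models$plsda
    map_model$preprocess <- preprocess_tag(pspec)
    mcube <- preprocess_cube(masked, pspec)
    chemical_map(mcube, map_model)
  })
  stage("map", render_map(map, file.path(out_dir, "severity_map.png")))

  invisible(list(summary = summary_df, partitions = partitions,
                 duncan = duncan, models = models, selection = selection,
                 map = map, out_dir = out_dir, config_hash = hash))
}
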