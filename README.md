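# canopyspec

Severity classification and pixel-wise chemical mapping of abiotic plant
stress from VNIR hyperspectral image cubes.

Root crops such as potato and sweet potato respond to drought, heat and
waterlogging with spectral changes that precede visible symptoms: pigment
loss raises visible reflectance (chlorophyll/carotenoid absorption near 450
and 670 nm weakens), tissue and water loss lower the NIR plateau
(730–900 nm), and the red edge (~690–740 nm) deforms. `canopyspec` turns a
raw 194-band (511–900 nm) cube of a potted plant into a per-pixel stress
severity map, for plant phenotyping researchers and chemometricians who
want each stage as a tested, composable function.

The chain, each stage exposed as R functions:

| stage | core |
|---|---|
| calibration | `X_cal = (X_raw − X_dark) / (X_white − X_dark)` |
| segmentation | false colour at 679.7/790.9/871.7 nm → HSV thresholds H 0.223–0.412, S 0.762–1.0, V 0.001–1.0 |
| ROI extraction | mean spectra of non-overlapping canopy patches |
| preprocessing | SNV, MSC, Savitzky–Golay (smooth / 2nd derivative), max/mean/range normalisation, PCA |
| indices | NDVI, RDVI = (NIR−R)/√(NIR+R), GNDVI, MCARI; ANOVA + Duncan letters |
| band selection | successive projections algorithm (SPA), validation-accuracy scored |
| classifiers | PLS-DA (NIPALS, exportable β), shrinkage LDA δᵢ(x) = xᵀΣ⁻¹μᵢ − ½μᵢᵀΣ⁻¹μᵢ + log πᵢ, one-vs-rest RBF-SVM f(x) = Σ αᵢyᵢK(xᵢ,x) + b |
| chemical map | per-pixel scores X·β + β₀, 0.5 class-boundary threshold, blue→green/yellow rendering |

PLS-DA regresses one-hot class labels on spectra through latent variables
maximising X–Y covariance (`X = TPᵀ + E_x`, `Y = UQᵀ + E_y`, default 10
LVs); its β coefficients applied pixel-wise produce the chemical image.
Splits are stratified 60/20/20 (calibration/validation/test) with
largest-remainder rounding; LDA and SVM hyperparameters are tuned by
stratified 5-fold cross-validation on the calibration set only.

Because the greenhouse cubes this analysis was designed for are available
only on request, the package includes a seeded synthetic generator
(`render_scene()`, `sample_spectra_table()`) that emulates stressed-canopy
reflectance — red edge, water bands, severity-dependent visible/NIR shifts,
scatter distortions, a spectrally distinct soil background — so the entire
pipeline runs and is tested without any external data. See the
`severity-mapping` vignette for the model, its assumptions and its limits.

## Worked example

Train on synthetic ROI spectra, segment a synthetic scene, map it:

```r
library(canopyspec)
grid <- default_grid()                                   # 194 bands, 511-900 nm
tbl <- sample_spectra_table(c(control = 200, early = 200, severe = 200),
                            grid = grid, seed = 1)
tbl <- stratified_split(tbl, seed = 1)                   # 60/20/20
pp <- preprocess_table(tbl, preprocess_spec("snv"))

cal <- pp$table$split == "cal"; test <- pp$table$split == "test"
model <- fit_plsda(pp$table$X[cal, ], pp$table$labels[cal], n_lv = 10)
model$preprocess <- "snv"
pred <- predict_plsda(model, pp$table$X[test, ])
evaluate(pp$table$labels[test], pred$category, pred$scores, set_name = "test")
#> <eval_report: test> accuracy 100.00%, macro P 1.000 R 1.000 F1 1.000, AUC 1.000
#>          predicted
#> truth     control early severe
#>   control      40     0      0
#>   early         0    40      0
#>   severe        0     0     40

scene <- render_scene(scene_spec(seed = 2), grid)        # 3 severity bands
refl <- calibrate_cube(scene$raw, scene$white, scene$dark)
mask <- segment_plant(build_pseudocolor(refl))           # published HSV thresholds
#> <plant_mask> 64x64, 1579 foreground pixels
cube <- preprocess_cube(apply_mask(refl, mask), pp$spec)
round(classify_map(chemical_map(cube, model))$fractions, 3)
#> uncertain   control     early    severe
#>     0.028     0.304     0.381     0.287
```

The held-out test spectra classify perfectly (the synthetic severities are
well separated), and the mapped scene recovers its three roughly equal
severity bands, with ~3 % of pixels — mostly at band boundaries — falling
below the 0.5 confidence threshold. Vegetation indices decline with
severity and Duncan grouping separates all three treatments:

```r
idx <- compute_indices(tbl)
anova_duncan(idx$NDVI, idx$treatment)
#> One-way ANOVA: F(2, 597) = 309.002, p = 7.62e-93; Duncan letters at alpha = 0.05
#>  treatment   n      mean letters
#>    control 200 0.7420097       a
#>      early 200 0.7194920       b
#>     severe 200 0.5786074       c
```

`run_pipeline()` executes the whole chain from one (optionally YAML)
config and writes summary tables, band selections and a rendered severity
map; `inst/scripts/canopyspec.R` wraps it for the shell.

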