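---
title: "Hyperspectral stress-severity classification and chemical mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral stress-severity classification and chemical mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyspec)
```

## The problem

Drought, heat and waterlogging change a leaf's optical properties before
visible symptoms appear: chlorophyll and carotenoid loss raises reflectance
in the visible range (the pigments absorb strongly near 450 and 670 nm),
structural damage and water loss lower the near-infrared (NIR) plateau
(730--900 nm), and the red edge — the steep rise between ~690 and 740 nm —
deforms. A frame-based VNIR camera samples this with ~194 narrow bands
between 511 and 900 nm, giving an H x W x B reflectance cube per plant.

`canopyspec` implements the full analysis chain for such cubes:

1. radiometric calibration against white/dark references,
2. pseudo-colour HSV segmentation of the canopy,
3. ROI spectral extraction,
4. scatter-correction preprocessing,
5. vegetation indices with ANOVA/Duncan grouping,
6. successive-projections (SPA) wavelength selection,
7. PLS-DA / shrinkage-LDA / RBF-SVM severity classifiers, and
8. pixel-wise "chemical maps" of stress severity from PLS-DA coefficients.

Because the greenhouse cubes this pipeline targets are not publicly
deposited, the package ships a first-class synthetic generator that
emulates their statistical structure; everything downstream is exercised
and tested against it.

## Models and procedures

### Calibration and segmentation

Reflectance is `(raw - dark) / (white - dark)` element-wise, clipped to
`[0, 1.5]`: a Teflon white tile is only ~99 % reflective, so specular
pixels legitimately exceed 1, while values far above that indicate a
calibration fault. Segmentation builds a false-colour composite from the
bands nearest 679.7, 790.9 and 871.7 nm, passes each channel through a
3 x 3 median filter (the edge-preserving "enhancement" that keeps
single-pixel sensor noise from scattering the HSV distribution), min--max
rescales each channel independently, converts to HSV on the unit scale and
keeps pixels inside hue 0.223--0.412, saturation 0.762--1.0, value
0.001--1.0. Connected components smaller than `min_object_px = 64` pixels
are discarded; the threshold is an addition of this package, since some
rule is needed to realise a "refined" mask and isolated in-range specks are
virtually always noise.

### Preprocessing

All operators are per-spectrum (row-wise) and therefore apply identically
to a table of ROI spectra and, pixel-wise, to a cube — a property the
chemical-imaging stage depends on and the tests assert. SNV centres and
scales each spectrum (sample SD, n − 1). MSC regresses each spectrum on a
reference and inverts the fitted affine distortion; the reference is frozen
from the calibration rows and reused everywhere else, so validation, test
and image pixels see exactly the transform the model was trained with and
no information leaks backwards. Savitzky--Golay smoothing defaults to
window 11, degree 2, and the second derivative to window 11, degree 3
(the sources state neither; both are conventional for ~2 nm sampling and
configurable, and the applied parameters are recorded in the provenance
trace). Derivatives are exact for polynomials up to the fitting degree,
including at the boundaries, which are handled by the first/last window
fits. PCA is column-centred only, computed on the same preprocessed spectra
used for visualisation.

### Vegetation indices

NDVI, RDVI, GNDVI and MCARI use the conventional narrowband positions (red
670, green 550, red-edge 700, NIR 800 nm) resolved by nearest band. The
printed RDVI formula in the source material is typographically identical to
NDVI; the standard form with the square-root denominator is used, and
`rdvi_as_printed = TRUE` reproduces the literal equation. Duncan's multiple
range test uses studentized-range quantiles at the protection level
`1 - (1 - alpha)^(p-1)` with the harmonic mean group size, assigning
letters to maximal homogeneous runs of the ordered means — so letter groups
are always contiguous in mean order. Shapiro--Wilk and Levene checks are
available as optional reporting only and never gate the ANOVA.

### Band selection and classifiers

`spa_chain()` is classical SPA: starting from a candidate band, repeatedly
deflate all columns by the chosen direction and append the column of
largest residual norm (ties to the lowest index). Because the sources do
not state how chain length and start were scored, `spa_select()` scores
every `(start, k)` prefix by the validation accuracy of a PLS-DA fitted on
those bands — consistent with how every other choice in the pipeline is
made — with ties to the smaller subset, then the lower start. Columns are
standardised on calibration statistics before projection. The search over
all starts is exhaustive by default with a `starts` subsample for speed.

PLS-DA is NIPALS PLS2 against one-hot labels; the regression coefficients
`beta = W (P'W)^{-1} Q'` are exportable and, at full rank, equal ordinary
least squares (asserted at 1e-8). Ten latent variables is the default, the
count the source analyses settled on; `select_plsda_lv()` picks by
validation accuracy up to 15. Class assignment is arg-max of the continuous
scores; the conventional 0.5 decision threshold is retained as a
per-sample confidence flag and as the class-boundary rule in maps, because
a hard ±0.5 rule alone leaves multi-class ties undefined. LDA uses a pooled
covariance shrunk toward `tr(Sigma)/p * I` with the weight chosen by
stratified 5-fold CV on the calibration set (grid 0, 0.01, 0.1, 0.3, 0.5 —
unstated in the sources, spanning none-to-half shrinkage). The SVM is
one-vs-rest with an RBF kernel, cost grid 0.1--100 and gamma scaled around
`1/(p * mean variance)`, CV-tuned the same way. The validation set is
reserved for latent-variable and band selection; the test set is never
touched before evaluation.

### Chemical maps

A fitted PLS-DA's beta coefficients applied to every (identically
preprocessed) foreground pixel give an H x W x C score cube; arg-max scores
above 0.5 become class labels, lower winners are "uncertain" (rendered
grey), background is excluded. A provenance string recorded by every
preprocessing step is compared between cube and model and any mismatch is a
hard error — a map built on differently preprocessed spectra is numerically
valid-looking but scientifically meaningless. Rendering maps severity rank
onto a blue-to-green/yellow gradient (blue = healthy) and writes the colour
contract to a sidecar JSON.

## The synthetic generator

`make_endmember()` builds canopy spectra from a low visible baseline with a
green bump at 550 nm, a logistic red edge rising to a 0.52 NIR plateau, and
Gaussian water absorptions at 742 and 842 nm. A severity profile lifts the
visible window multiplicatively (`vis_gain`, 520--700 nm), scales the NIR
(`nir_loss`, >= 740 nm, linear blend between), moves the red-edge
inflection and sets the water-band depth.

The default study conditions, chosen once:

| profile | vis_gain | nir_loss | red-edge shift | water depth |
|---------|----------|----------|----------------|-------------|
| control | 1.00     | 1.00     |  0 nm          | 0.050       |
| early   | 1.05     | 0.95     | +4 nm          | 0.038       |
| severe  | 1.50     | 0.85     | +12 nm         | 0.025       |

Three modelling decisions deserve explanation:

* **Red-edge direction.** Pure pigment loss blue-shifts the red-edge
  inflection of a single leaf. At canopy scale, however, the effective edge
  of a stressed stand also flattens as structure collapses, and in these
  profiles the inflection of the modelled edge retreats toward longer
  wavelengths with severity. Under a strictly multiplicative visible gain
  this is also the only parameterisation under which MCARI declines
  monotonically with severity alongside NDVI, RDVI and GNDVI — the
  behaviour the index trajectories of stressed potato stands actually show.
  A generator with a blue-shifting edge and uniform gain would make MCARI
  rise with stress.
* **Distinct stress directions.** Early stress is dominated by water
  status (shallower water bands, slight NIR loss, barely lifted visible);
  severe stress adds pigment collapse. The three class means therefore do
  not lie on one common gain axis. This matters: one-hot least-squares
  classifiers such as PLS-DA mask the middle class when class means are
  collinear, an artefact a naive generator induces but real canopy spectra
  do not show.
* **Background spectrum.** The default background is a dry-soil/bench
  spectrum, nearly flat through the visible and rising steeply beyond
  ~820 nm. A flat grey background would make the published HSV thresholds
  unsatisfiable: after per-channel rescaling the canopy would be the
  brightest surface in both NIR channels and land at cyan (hue 0.5),
  outside the 0.223--0.412 hue window. With the NIR-bright background the
  canopy of every severity renders green with high saturation, and the
  printed thresholds segment it; the background remains configurable.

Scenes apply the forward model `raw = dark + reflectance * (white - dark)`
plus optional per-pixel scatter and per-band Gaussian noise (default
SD 0.01 at pixel level), so calibration inverts the model exactly at zero
noise. Spectra-table rows emulate ROI-mean spectra — averages of ~25-pixel
patches — so their default noise is `0.01 / sqrt(25) = 0.002`, after a
per-row scatter distortion (slope U(0.8, 1.2), offset U(-0.05, 0.05)) that
SNV and MSC are designed to remove. Severity bands are stacked with the
most severe at the top of the canopy, mirroring the apical expression of
drought symptoms.

What the generator does **not** emulate: radiative-transfer realism
(PROSPECT/SAIL), 3-D canopy geometry and shading, illumination BRDF,
mixed soil/leaf boundary pixels, sensor striping or drift, and biological
within-class variation beyond scatter and noise. Passing tests therefore
demonstrate that the implementation recovers known structure under the
stated conditions — not that the trained models would transfer to real
greenhouse imagery.

## Worked example

```{r example, eval = FALSE}
grid <- default_grid()
tbl <- sample_spectra_table(c(control = 200, early = 200, severe = 200),
                            grid = grid, seed = 1)
tbl <- stratified_split(tbl, seed = 1)
pp <- preprocess_table(tbl, preprocess_spec("snv"))

cal <- pp$table$split == "cal"
model <- fit_plsda(pp$table$X[cal, ], pp$table$labels[cal], n_lv = 10)
model$preprocess <- "snv"

scene <- render_scene(scene_spec(seed = 2), grid)
refl <- calibrate_cube(scene$raw, scene$white, scene$dark)
mask <- segment_plant(build_pseudocolor(refl))
cube <- preprocess_cube(apply_mask(refl, mask), pp$spec)
map <- chemical_map(cube, model)
classify_map(map)$fractions
```

Or run every stage at once with `run_pipeline()`; see the README for the
numbers a default run prints.

## Numerical choices and degenerate inputs

Split sizes use largest-remainder rounding with ties resolved toward the
earlier set (calibration, then validation, then test); this reproduces the
published partition sizes exactly, including 6558 spectra splitting as
3935/1312/1311. Band lookup resolves distance ties toward the lower
wavelength. A constant image plane rescales to zero rather than NaN. An
empty segmentation returns an empty mask with a warning, not an error, so a
pipeline can report the failure. Zero-variance rows in SNV, degenerate rows
in the normalisations, near-zero MSC slopes (|b| < 1e-8), white <= dark
calibration references, band-count mismatches in prediction and
preprocessing-provenance mismatches in mapping are all hard errors naming
the offending row/pixel/band. SPA chains truncate with a warning when the
candidate span is exhausted (duplicated columns project to zero and are
never selected). LDA grid points with a singular covariance are skipped
with a warning rather than failing the fit.

## Problem sizes

The test suite and acceptance script use scaled-down problem sizes chosen
to exercise every code path at desk scale: 194-band grids for anything
touching band lookup or segmentation, 8--60-band grids for operator
algebra, scenes of 32--64 pixels per side, tables of 600 spectra
(200 per severity), ten-seed replication for the stochastic recovery
experiment, and an SPA search over the published subset-size range 21--32
from 8 chain starts. These sizes are the package's own defaults for a
reproducible desk run; all of them are configurable upward.

## Known limitations

* The synthetic severity classes are far better separated than real
  cultivar data; published accuracies of 90--98 % correspond here to
  near-perfect recovery, so the acceptance checks are lower bounds on
  implementation correctness, not benchmarks of field performance.
* SPA scoring refits a PLS-DA for every (start, k) candidate; exhaustive
  starts over 194 bands is O(B * k_max) fits and is the slowest stage at
  full scale. Use the `starts` argument for large grids.
* The vendor's exact non-uniform band centres are not public; the working
  grid is evenly spaced and `senop_known_wavelengths()` carries only the
  printed subset.
* Duncan letter assignment uses the standard maximal-homogeneous-run
  shortcut; for highly unbalanced designs the harmonic-mean group size is
  an approximation.
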