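# vinespec

Chemometric pipeline for predicting grapevine midday **stem water potential**
(psi_s, MPa) from **on-the-go near-infrared spectra**, with a synthetic
campaign generator for end-to-end testing.

Stem water potential is the gold-standard plant water-status indicator in
viticulture, but pressure-chamber measurement is slow and destructive.
Driving a NIR spectrometer (1100–2100 nm, 4 nm resolution, 24 Hz) along the
rows at 5 km/h yields thousands of canopy reflectance spectra per pass; the
depth of the water (OH) absorption bands near 1450 and 1940 nm tracks leaf
water content, so psi_s can be calibrated against spectra with partial least
squares regression. `vinespec` implements the whole workflow:

1. **Synthetic campaigns** — a randomized block trial (4 blocks x 3
   irrigation regimes, 9 or 6 dates), per-treatment psi_s trajectories,
   weather (VPD by Tetens), and 24 Hz spectral streams with an affine
   band-depth signal `depth = alpha0 + alpha1 * psi`, realistic nuisance
   variation, and wood/metal/gap contaminants with truth tags.
2. **Stream processing** — leaf-signature filtering (Pearson correlation
   threshold on SNV-normalised spectra), allocation of each row pass into
   three contiguous 5-vine sub-replicate units, group averaging.
3. **Preprocessing** — standard normal variate and Savitzky–Golay
   derivatives via shorthand codes (`"SNV+D1W15"`, `"D1W7"`).
4. **QC** — PCA with Q residuals and Hotelling T² (limit
   `p(n-1)/(n-p) F_{p,n-p,alpha}`; Jackson–Mudholkar Q limit), single-pass
   removal on the OR rule.
5. **Calibration** — NIPALS PLS1 (mean-centred), stratified 80/20 split,
   10-fold venetian-blind and leave-one-day-out cross-validation,
   latent-variable selection at minimum CV-RMSE, external prediction with
   R² and RMSE.
6. **Mapping** — multilevel B-spline approximation of predicted psi_s at
   sub-unit centroids, ESRI ASCII grid export.

Data objects are Bioconductor-style S4: spectra live in a `SpectraBatch`
(a `SummarizedExperiment` with wavelengths as rows and acquisition metadata
as `colData`), paired spectra/reference samples in a `CalibrationDataset`,
models in `PCAModel`/`PLSModel`, rasters in `MapGrid`.

## Worked example

Simulate the default 2015-style east-side campaign (324 sub-replicate
samples built from ~56,000 raw stream spectra) and run the full pipeline:

```r
library(vinespec)
res <- runPipeline(defaultConfig(seed = 1))
res$report
#>  n_scale n_removed n_calibration n_external nLV
#>      324        35           238         51   7
#>  RMSEC   Rc2 CV_RMSE_venetian Rcv2_venetian CV_RMSE_lodo Rcv2_lodo RMSEP   Rp2
#>  0.132 0.874            0.157         0.824        0.278     0.444 0.157 0.815
```

Reading the report: of 324 sub-replicate mean spectra, 35 were removed as
atypical by Q/T² (10.8%); the model selected 7 latent variables at the
venetian CV-RMSE minimum; calibration fit R² = 0.87 with RMSE 0.132 MPa;
interleaved 10-fold cross-validation gives R² = 0.82, while leave-one-day-out
is markedly worse (CV-RMSE 0.278 vs 0.157 MPa) because day-level conditions
confound the spectra — exactly the pattern that motivates keeping a few
reference measurements per new day. On the untouched external 20%
(51 samples) the model predicts psi_s with R² = 0.815 and RMSE 0.157 MPa,
against a seasonal psi_s range of roughly −0.55 to −2.25 MPa.

Map the predicted water status of one date and export it:

```r
g <- psiMap(res, date = "2015-08-12", cellSize = 0.5)
g
#> MapGrid: 174 x 26 cells of 0.5 m, origin (9.1, 2.1), range -1.632..-0.691
exportGrid(g, "psi_2015-08-12.asc")
```

Individual stages are exported too, e.g.

```r
vpd(32.0, 36.5)                    # 3.02 kPa
nChannels(makeGrid(1100, 2100, 4)) # 251
venetianFolds(10, 5)               # 1 2 3 4 5 1 2 3 4 5
applyPreprocess(x, "SNV+D1W15", step = 4)
```

## Layout

```
R/                 implementation (S4 classes, generator, pipeline stages)
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette (model, assumptions, design choices)
scripts/           acceptance script (see above)
```
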