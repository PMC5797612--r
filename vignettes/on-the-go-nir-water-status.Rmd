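---
title: "Modelling grapevine water status from on-the-go NIR spectra"
author: "vinespec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling grapevine water status from on-the-go NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinespec)
```

## The problem

Midday stem water potential (psi_s, MPa, negative) is the reference
indicator of plant water status in viticulture, but measuring it with a
pressure chamber is slow and destructive: a leaf is bagged, dark-adapted
for an hour, cut, and pressurised. A contactless alternative is to drive a
near-infrared (NIR) spectrometer along the rows and predict psi_s from
canopy reflectance: leaf tissue is mostly water, and the OH absorption
bands near 1450 nm (first overtone) and 1940 nm (combination band) deepen
as leaf water content rises. `vinespec` implements the full chemometric
pipeline for that idea — from raw 24 Hz spectral streams acquired at
5 km/h to calibrated partial least squares (PLS) models and maps of
predicted water status — together with a synthetic campaign generator that
emulates the field trial the method was validated on, so every stage is
testable without field data.

## The emulated experiment

The generator reproduces a completely randomized block design: 4 blocks x
3 irrigation regimes (T0 full, T1 moderate, T2 none), i.e. 12 field
replicates. Each replicate is a monitored row of 25 vines spaced 1.20 m;
only the middle 15 vines are measured, as three contiguous 5-vine
*sub-replicate units*. One tagged vine per sub-unit carries the
pressure-chamber reference, so one campaign yields
`12 x 3 x (number of dates)` reference values: 324 over the 9 dates of the
2015-style season and 216 over the 6 dates of the 2016-style season.

Reference psi_s values are drawn per treatment and date from Gaussian
trajectories that are hard-clipped to each treatment's observed bounds.
The per-date means follow the qualitative seasonal course of the two
campaigns (drying into mid August, partial recovery after early-September
rain, steady decline for the unirrigated regime); only the pooled
per-treatment min/max/mean/SD are treated as quantitative constraints, and
the split between seasonal movement and within-date scatter is controlled
by `dateShareSD` (default 0.6: 60% of the pooled SD lives in the date
means, the remainder within dates — pooling over dates recovers the total).

Weather for the built-in seasons is stored as solar-noon air temperature
and relative humidity per date; vapour pressure deficit is computed with
the Tetens saturation formula over liquid water,
`es = 0.6108 exp(17.27 T / (T + 237.3))`, `VPD = es (1 - RH/100)`. This
reproduces the recorded VPD values to within about 1% for almost all
dates; one 2016 date (18.7 degrees C, 48.5% RH, recorded 1.31 kPa) is not
reproducible by any standard saturation formula and is not used as a
check.

## The spectral stream model

A pass along one replicate at speed v and acquisition rate r emits
`round(r * L / v)` spectra over the 30 m row (518 at the default 24 Hz and
5 km/h, about 17.3 spectra per metre). Each leaf spectrum on the
1100–2100 nm, 4 nm grid (251 channels) is

```
A(lambda) = baseline + scatter * [ M(lambda) + depth(psi) * B(lambda) + g_date(lambda) ] + noise
```

where `M` is a fixed leaf "matrix" background (two broad minor bands over
a flat base), `B` is the water-band shape (Gaussian bands at 1450 and
1940 nm, widths 40 and 60 nm, relative heights 1 and 0.85) and the band
depth is affine in the vine's stem water potential,
`depth = alpha0 + alpha1 * psi` with `alpha1 > 0`: wetter (less negative)
vines absorb more. Additive baseline and multiplicative scatter are drawn
per spectrum; SNV is designed to remove exactly this kind of variation.

Error structure matters more than the signal itself, because it decides
what performance the downstream model can attain. Four terms are built in:

* **within-sub-unit heterogeneity** (`vineSD`, 0.10 MPa): untagged vines
  deviate from the sub-unit reference;
* **reference representativity** (`tagSD`, 0.15 MPa): the whole sub-unit
  canopy is offset from the bagged reference leaf by a shared draw — this
  term does not average out over the ~100 spectra of a sub-unit and sets
  the irreducible prediction floor;
* **day-level confounding** (`dateDepthSD`, 0.03 absorbance units, and
  `dateSpectralSD`, 0.02): a per-date band-depth offset plus smooth
  per-date spectral clutter shared by every spectrum of the date. These
  mimic changing ambient conditions; they are what makes leave-one-day-out
  validation genuinely harder than interleaved validation;
* **per-spectrum terms**: leaf-to-leaf depth jitter (0.03) and i.i.d.
  channel noise (SD 0.02).

A fraction of emitted spectra (default 0.15) are contaminants — wood (one
broad 1200 nm band), metal posts (flat low absorbance) and canopy gaps
(near-zero signal, noisy). Every spectrum carries its truth class and
sub-unit, so filtering and QC can be scored against ground truth. These
defaults were fixed once so that the reference pipeline lands at an
external R2 of about 0.8 — the middle of the performance envelope the
method reports on real data — and were not revisited afterwards.

What the generator deliberately does not model: radiative transfer in the
leaf (no PROSPECT-style optics), 3-D canopy geometry, within-day psi_s
dynamics, vine identity persisting across dates, or any difference between
east and west canopy sides beyond independent draws. Passing tests
therefore show that the pipeline recovers the statistical structure this
model encodes — an affine band-depth signal under realistic nuisance
variation — not that it would attain the same numbers on any particular
vineyard.

## The analysis pipeline

`runPipeline()` executes the stages in a fixed order:

1. **Signature filtering** (raw stream): Pearson correlation of each
   spectrum with a static leaf signature, threshold 0.90, plus mean
   absorbance gates (0.05–2.5). Correlation is computed on centred/scaled
   spectra, so SNV-normalising first is implied. Filtering runs *before*
   averaging — its purpose is to keep gaps, wood and metal out of the leaf
   averages.
2. **Positional trimming and allocation**: spectra from the middle 15
   vines (positions are implied by constant vehicle speed) are split into
   three contiguous, order-preserving groups of near-equal size (earlier
   groups take the remainder) and each group is averaged into one spectrum
   per sub-replicate unit, linked to its reference psi_s.
3. **Preprocessing**: shorthand codes such as `"SNV+D1W15"` — standard
   normal variate (per-spectrum centring/scaling, sample SD) followed by a
   Savitzky-Golay first derivative, window 15 channels, polynomial order
   2. Derivatives are scaled per nm; edge channels are dropped rather than
   padded (237 channels survive a W15 derivative), so no edge artefacts
   enter the model. Window sizes are channel counts, the conventional
   chemometric reading of "W7"/"W15".
4. **Outlier removal**: PCA (components capturing 95% of variance, capped
   at 10) with Q residuals (distance to the model plane) and Hotelling
   T-squared (distance within it). Limits: Jackson-Mudholkar for Q (with
   an empirical-quantile fallback when the residual moments degenerate)
   and `p(n-1)/(n-p) F_{p,n-p,alpha}` for T-squared at alpha = 0.95. A
   sample is removed when *either* statistic exceeds its limit, in a
   single pass on the full dataset before splitting — matching a one-shot
   removal-percentage report; the OR rule and the PC count are our
   choices where the procedure is underdetermined.
5. **Split and validation**: stratified (date x treatment x side)
   pseudorandom 80/20 calibration/external split; 10-fold venetian-blind
   cross-validation (sample k to fold k mod 10, after ordering by date,
   side, replicate, sub-unit) and leave-one-day-out cross-validation; the
   latent-variable count minimises the venetian CV-RMSE (ties to fewer),
   and external prediction always uses that count — LODO is reported as a
   robustness diagnostic only.
6. **PLS**: NIPALS PLS1, mean-centred but not variance-scaled (the usual
   choice for derivative spectra), up to 15 latent variables. R2 is
   `1 - SS_res/SS_tot` about the evaluation set's own mean, not a squared
   correlation. Within each CV fold the centring is refit on the training
   fold; SNV and derivatives are per-spectrum operations and carry no
   training state, so they cannot leak.

Two scales are supported: the native sub-replicate scale (three samples
per replicate and date) and the field-replicate scale, where the three
sub-unit spectra and psi_s values are averaged per replicate and the
identical pipeline runs on one third the samples. A balanced two-side
dataset can be formed by drawing equal numbers per (side, treatment, date)
cell from the east and west datasets.

## Mapping

Predicted psi_s values, placed at sub-unit centroids in a local plot frame
(metres), are interpolated with multilevel B-spline approximation (MBA):
uniform cubic B-spline control lattices, starting from a 4 x 4 control
lattice and refining dyadically, each level fitted (BA algorithm) to the
residuals of the coarser levels; the global mean is the level-0 surface,
so constant fields are reproduced exactly. Per-level residuals are
tracked as RMS at the data points, which decreases monotonically across
levels; the pointwise max-norm can wiggle at coarse lattices where the
surface cannot yet resolve neighbouring points, and data-point
reproduction to a 1e-3 fraction of the value range at 8 levels requires
the points to be separated by more than the finest lattice support. Grids
export as plain-text ESRI ASCII rasters.

## Numerical choices and degenerate inputs

* PCA and PLS are deterministic: SVD-based PCA fixes each component's sign
  so its largest-magnitude loading is positive; NIPALS PLS1 is closed-form
  per latent variable (the 1e-12/500-iteration controls only matter for a
  multi-response generalisation).
* `snv` refuses constant spectra; `plsFit` refuses a constant response and
  demands `nLV <= min(n - 1, channels)`; cross-validation caps the tested
  complexity at what the smallest training fold supports and, if a
  training fold exhausts rank early, reuses the deepest available fit for
  higher counts.
* Allocation of a stream into sub-units is positional (contiguous
  near-equal thirds) rather than timestamp-based, justified by constant
  vehicle speed; remainders go to the earliest groups to make the rule
  deterministic.
* All randomness flows from one campaign seed through deterministic
  per-operation sub-seeds, so psi draws, streams, splits and merges are
  bit-reproducible and independent stages do not perturb each other.

## Problem sizes used in the checks

The package's own test suite runs the full default 2015-style east-side
campaign (324 sub-replicate samples from roughly 56,000 simulated raw
spectra) across 10 seeds for the headline performance check, and smaller
campaigns (2 blocks, 2–4 dates) for structural and reproducibility tests.
Those sizes are the package's choice of a representative yet quick
configuration; the generator scales to arbitrary designs.

## Known limitations

* The synthetic leaf model is phenomenological; absolute absorbance levels
  and band shapes are plausible rather than physically derived.
* Reflectance-to-absorbance conversion, vendor binary formats, wavelength
  resampling, MSC/OSC/detrending pretreatments and robust PCA variants are
  out of scope.
* Outlier removal is single-pass by design; iterating it would change the
  removal percentages.
* The east/west distinction in the generator is purely nominal; real
  canopies differ systematically between sides.
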