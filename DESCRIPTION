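Package: vinespec
Title: On-the-Go NIR Spectroscopy Pipeline for Grapevine Stem Water Potential
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric pipeline for predicting midday stem water potential
    (psi_s, MPa) of grapevines from on-the-go near-infrared reflectance
    spectra (1100-2100 nm). Provides synthetic campaign generation emulating a
    randomized block irrigation trial with 24 Hz spectral streams, stream
    allocation to sub-replicate units and group averaging, signature-spectrum
    contaminant filtering, standard normal variate and Savitzky-Golay
    preprocessing, PCA-based outlier rejection via Q residuals and Hotelling
    T-squared, NIPALS PLS1 calibration with venetian-blind and
    leave-one-day-out cross-validation, external prediction metrics, and
    spatial mapping of predicted water status through multilevel B-spline
    approximation with ESRI ASCII grid export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    signal,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
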