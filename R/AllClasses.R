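#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor qf qnorm quantile rnorm runif sd var lm coef predict
#' @importFrom utils head read.csv write.csv
NULL

#' Regular wavelength grid
#'
#' An inclusive, regularly spaced wavelength axis in nanometres. The
#' instrument emulated here covers 1100--2100 nm at 4 nm resolution, i.e.
#' 251 channels.
#'
#' @slot start first wavelength (nm)
#' @slot stop last wavelength (nm)
#' @slot step channel spacing (nm)
#' @seealso [makeGrid()], [wavelengths()], [nChannels()]
#' @exportClass WavelengthGrid
setClass("WavelengthGrid",
  representation(start = "numeric", stop = "numeric", step = "numeric"))

setValidity("WavelengthGrid", function(object) {
  msg <- character()
  if (length(object@start) != 1L || length(object@stop) != 1L ||
      length(object@step) != 1L)
    msg <- c(msg, "start, stop and step must be scalars")
  else {
    if (!(object@stop > object@start)) msg <- c(msg, "stop must exceed start")
    if (!(object@step > 0)) msg <- c(msg, "step must be positive")
    span <- object@stop - object@start
    if (abs(span / object@step - round(span / object@step)) > 1e-9)
      msg <- c(msg, "(stop - start) must be divisible by step")
  }
  if (length(msg)) msg else TRUE
})

#' Batch of on-the-go spectra
#'
#' A `SpectraBatch` is a \linkS4class{SummarizedExperiment} holding one
#' absorbance assay with wavelengths in rows and spectra (acquisition order
#' preserved) in columns. Per-spectrum acquisition metadata live in
#' `colData`: `date`, `side` ("east"/"west"), `replicate_id`, `sub_unit`,
#' `timestamp` (s), `position_m` (distance along the row) and `class_tag`
#' (generator truth label, `NA` for real data). The shared
#' \linkS4class{WavelengthGrid} is stored in `metadata(x)$grid`.
#'
#' @seealso [SpectraBatch()], [absorbance()], [spectraGrid()],
#'   [allocateStream()], [averageSpectra()]
#' @exportClass SpectraBatch
setClass("SpectraBatch", contains = "SummarizedExperiment")

.metaColumns <- c("date", "side", "replicate_id", "sub_unit",
                  "timestamp", "class_tag", "position_m")

setValidity("SpectraBatch", function(object) {
  msg <- character()
  grid <- S4Vectors::metadata(object)$grid
  if (!is(grid, "WavelengthGrid"))
    return("metadata(x)$grid must be a WavelengthGrid")
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'absorbance' is required")
  else {
    a <- SummarizedExperiment::assay(object, "absorbance")
    if (nrow(a) != nChannels(grid))
      msg <- c(msg, sprintf("assay has %d rows but grid has %d channels",
                            nrow(a), nChannels(grid)))
    if (ncol(a) && !all(is.finite(a)))
      msg <- c(msg, "all absorbance values must be finite")
  }
  miss <- setdiff(.metaColumns, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Synthetic vineyard trial design
#'
#' Encodes a completely randomized block design: `blocks` x `treatments`
#' field replicates, each a monitored row of 25 vines of which the middle 15
#' are measured, partitioned into three 5-vine sub-replicate units, each with
#' one tagged vine whose midday stem water potential is the reference value.
#'
#' @slot blocks number of blocks
#' @slot treatments treatment labels (e.g. T0/T1/T2 irrigation regimes)
#' @slot dates ordered campaign dates (character)
#' @slot vinesPerReplicate vines in the monitored row (25; middle 15 measured)
#' @slot subUnitsPerReplicate sub-replicate units per replicate (3)
#' @slot taggedVinesPerReplicate tagged vines per replicate (3, one per sub-unit)
#' @slot vineSpacing vine spacing along the row (m)
#' @slot rowSpacing spacing between rows (m)
#' @slot layout data.frame of replicates: replicate_id, block, treatment,
#'   and the plot-frame origin (x0, y0) of the monitored row
#' @seealso [buildDesign()], [designTable()], [referenceSlots()]
#' @exportClass FieldDesign
setClass("FieldDesign",
  representation(blocks = "integer", treatments = "character",
                 dates = "character", vinesPerReplicate = "integer",
                 subUnitsPerReplicate = "integer",
                 taggedVinesPerReplicate = "integer",
                 vineSpacing = "numeric", rowSpacing = "numeric",
                 layout = "data.frame"))

setValidity("FieldDesign", function(object) {
  msg <- character()
  if (object@blocks < 1L) msg <- c(msg, "need at least one block")
  if (!length(object@treatments)) msg <- c(msg, "need at least one treatment")
  if (!length(object@dates)) msg <- c(msg, "need at least one date")
  if (nrow(object@layout) !=
      object@blocks * length(object@treatments) * object@subUnitsPerReplicate)
    msg <- c(msg, "layout must have one row per replicate sub-unit")
  if (object@taggedVinesPerReplicate != object@subUnitsPerReplicate)
    msg <- c(msg, "one tagged vine per sub-replicate unit is assumed")
  if (length(msg)) msg else TRUE
})

#' Paired spectra/reference calibration dataset
#'
#' Rows of `X` are (possibly preprocessed) mean spectra of sub-replicate
#' units; `y` holds the matching stem water potential references (MPa,
#' negative); `labels` carries date, side, treatment, replicate_id, sub_unit
#' and plot coordinates for each sample.
#'
#' @slot X numeric matrix, samples x channels
#' @slot y numeric vector of psi_s references (MPa, negative)
#' @slot labels data.frame of per-sample labels
#' @slot grid the \linkS4class{WavelengthGrid} of the columns of `X`
#' @seealso [calibrationDataset()], [runPipeline()]
#' @exportClass CalibrationDataset
setClass("CalibrationDataset",
  representation(X = "matrix", y = "numeric", labels = "data.frame",
                 grid = "WavelengthGrid"))

setValidity("CalibrationDataset", function(object) {
  msg <- character()
  if (nrow(object@X) != length(object@y))
    msg <- c(msg, "nrow(X) must equal length(y)")
  if (nrow(object@labels) != length(object@y))
    msg <- c(msg, "labels must have one row per sample")
  if (ncol(object@X) != nChannels(object@grid))
    msg <- c(msg, "ncol(X) must match the grid channel count")
  if (length(object@y) && any(object@y >= 0))
    msg <- c(msg, "stem water potential must be negative (MPa)")
  if (length(object@y) && !all(is.finite(object@X)))
    msg <- c(msg, "X must be finite (no missing channels)")
  if (length(msg)) msg else TRUE
})

#' Principal component model for spectral QC
#'
#' Mean-centred PCA fitted by SVD, with the component sign fixed so the
#' largest-magnitude loading element of each component is positive. Retains
#' all eigenvalues (needed for the Jackson-Mudholkar Q limit) plus the first
#' `p` loadings used for scores and Hotelling T-squared.
#'
#' @slot center channel means of the training matrix
#' @slot loadings p x channels orthonormal loading matrix
#' @slot eigenvalues all score variances (d^2/(n-1)), length = rank
#' @slot n training sample count
#' @slot p number of retained components
#' @slot alpha confidence level for control limits
#' @slot trainingQ Q residuals of the training samples (empirical fallback)
#' @seealso [pcaFit()], [scoresQT2()], [qLimit()], [hotellingLimit()]
#' @exportClass PCAModel
setClass("PCAModel",
  representation(center = "numeric", loadings = "matrix",
                 eigenvalues = "numeric", n = "integer", p = "integer",
                 alpha = "numeric", trainingQ = "numeric"))

setValidity("PCAModel", function(object) {
  msg <- character()
  if (object@p < 1L || object@p > min(object@n - 1L, length(object@center)))
    msg <- c(msg, "need 0 < p <= min(n - 1, channels)")
  if (!(object@alpha > 0 && object@alpha < 1))
    msg <- c(msg, "alpha must be in (0, 1)")
  G <- object@loadings %*% t(object@loadings)
  if (max(abs(G - diag(nrow(G)))) > 1e-10)
    msg <- c(msg, "loadings must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' QC statistics for a set of spectra
#'
#' Per-sample Q residuals (squared distance to the PCA plane) and Hotelling
#' T-squared (Mahalanobis distance in score space), together with their
#' control limits. A sample is flagged when either statistic exceeds its
#' limit.
#'
#' @slot Q per-sample residual sum of squares
#' @slot T2 per-sample Hotelling statistic
#' @slot Qlimit Q control limit
#' @slot T2limit T-squared control limit
#' @slot outlier logical mask, `TRUE` where Q > Qlimit or T2 > T2limit
#' @seealso [scoresQT2()], [flagAndRemove()]
#' @exportClass QCResult
setClass("QCResult",
  representation(Q = "numeric", T2 = "numeric", Qlimit = "numeric",
                 T2limit = "numeric", outlier = "logical"))

setValidity("QCResult", function(object) {
  msg <- character()
  if (length(object@Q) != length(object@T2) ||
      length(object@Q) != length(object@outlier))
    msg <- c(msg, "Q, T2 and outlier must have equal length")
  if (any(object@Q < -1e-12) || any(object@T2 < -1e-12))
    msg <- c(msg, "Q and T2 must be non-negative")
  ref <- object@Q > object@Qlimit | object@T2 > object@T2limit
  if (length(object@outlier) && !identical(ref, object@outlier))
    msg <- c(msg, "outlier mask must equal (Q > Qlimit | T2 > T2limit)")
  if (length(msg)) msg else TRUE
})

#' NIPALS PLS1 regression model
#'
#' Mean-centred (not variance-scaled) partial least squares regression of a
#' single response on spectra. Weights, X-loadings and y-loadings are stored
#' per latent variable so predictions can be formed at any complexity up to
#' `maxLV`; `nLV` is the complexity selected by cross-validation.
#'
#' @slot xMean channel means
#' @slot yMean response mean
#' @slot W channels x maxLV weight matrix
#' @slot P channels x maxLV X-loading matrix
#' @slot q y-loadings, length maxLV
#' @slot coefficients regression vector at `nLV`
#'   (prediction = yMean + (x - xMean) %*% coefficients)
#' @slot nLV selected number of latent variables
#' @slot preprocess preprocessing shorthand the model expects (e.g. "SNV+D1W15")
#' @slot grid wavelength grid of the input channels
#' @seealso [plsFit()], [predictPsi()], [selectNLV()]
#' @exportClass PLSModel
setClass("PLSModel",
  representation(xMean = "numeric", yMean = "numeric", W = "matrix",
                 P = "matrix", q = "numeric", coefficients = "numeric",
                 nLV = "integer", preprocess = "character",
                 grid = "WavelengthGrid"))

setValidity("PLSModel", function(object) {
  msg <- character()
  if (object@nLV < 1L || object@nLV > ncol(object@W))
    msg <- c(msg, "nLV must be in 1..ncol(W)")
  if (ncol(object@W) != ncol(object@P) || ncol(object@W) != length(object@q))
    msg <- c(msg, "W, P and q disagree on the latent-variable count")
  if (length(msg)) msg else TRUE
})

#' Raster of interpolated water status
#'
#' A regular grid in the local plot frame (metres), values in MPa, row 1 of
#' `values` being the northern-most (largest y) row as in ESRI ASCII rasters.
#'
#' @slot xll x of the lower-left corner (m)
#' @slot yll y of the lower-left corner (m)
#' @slot cellSize cell size (m)
#' @slot values numeric matrix, nrows x ncols, top row first
#' @slot nodata marker written for missing cells on export
#' @seealso [mbaInterpolate()], [exportGrid()], [readGrid()]
#' @exportClass MapGrid
setClass("MapGrid",
  representation(xll = "numeric", yll = "numeric", cellSize = "numeric",
                 values = "matrix", nodata = "numeric"))

setValidity("MapGrid", function(object) {
  msg <- character()
  if (!(object@cellSize > 0)) msg <- c(msg, "cellSize must be positive")
  v <- object@values
  if (length(v) && any(!is.finite(v) & !is.na(v)))
    msg <- c(msg, "values must be finite or NA")
  if (length(msg)) msg else TRUE
})
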