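# run a pipeline stage with labelled diagnostics
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Default pipeline configuration
#'
#' Nested list understood by [runPipeline()]. Top-level `seed` drives every
#' random choice (campaign simulation and the 80/20 split). `simulate`
#' describes the synthetic campaign (used unless `input` points at spectra
#' and reference CSVs); `filter`, `preprocess`, `qc`, `split`, `cv` and
#' `scale` parameterize the analysis stages; `outdir` (optional) persists
#' stage outputs.
#'
#' @param ... replacements for individual defaults, e.g.
#'   `defaultConfig(seed = 7, preprocess = "D1W7")`
#' @return configuration list
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(season = "2015", side = "east", blocks = 4L,
                    stream = list()),
    input = NULL,
    filter = list(threshold = 0.90, gates = c(0.05, 2.5), psi = -1.0),
    preprocess = "SNV+D1W15",
    qc = list(alpha = 0.95, varExplained = 0.95, maxComponents = 10L),
    split = list(fraction = 0.8, strata = c("date", "treatment", "side")),
    cv = list(nFolds = 10L, maxLV = 15L),
    scale = "sub_unit",
    outdir = NULL)
  mods <- list(...)
  if (length(mods)) cfg <- utils::modifyList(cfg, mods)
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [defaultConfig()]
#' @return configuration list (defaults filled in)
#' @export
loadConfig <- function(path) {
  utils::modifyList(defaultConfig(), yaml::read_yaml(path))
}

# filter -> positional trim to the middle 15 vines -> allocate -> average;
# returns up to nGroups mean raw spectra (rows) with linked labels, or NULL
# if the stream yields no usable leaf spectra
.processStream <- function(stream, signature, filterCfg, design, psiRows) {
  filt <- signatureFilter(stream, signature, filterCfg$threshold,
                          filterCfg$gates)
  kept <- filt$retained
  if (nSpectra(kept) == 0L) return(NULL)
  pos <- spectraMeta(kept)$position_m
  if (!all(is.na(pos))) {
    vs <- design@vineSpacing
    lo <- 5 * vs
    hi <- (design@vinesPerReplicate - 5) * vs
    kept <- kept[, !is.na(pos) & pos >= lo & pos < hi]
  }
  nG <- design@subUnitsPerReplicate
  if (nSpectra(kept) < nG) return(NULL)
  groups <- allocateStream(kept, nG)
  rows <- lapply(seq_along(groups), function(u) {
    avg <- averageSpectra(groups[[u]])
    ref <- psiRows[psiRows$sub_unit == u, ]
    if (nrow(ref) != 1L) return(NULL)
    list(x = as.numeric(absorbance(avg)[, 1L]), y = ref$psi_MPa,
         label = data.frame(date = ref$date, side = spectraMeta(avg)$side,
                            treatment = ref$treatment, block = ref$block,
                            replicate_id = ref$replicate_id, sub_unit = u,
                            x = ref$x, y = ref$y))
  })
  rows[!vapply(rows, is.null, TRUE)]
}

# apply a preprocessing code to a dataset, trimming the grid to match
.preprocessDataset <- function(dataset, code) {
  steps <- parsePreprocess(code)
  X <- applyPreprocess(dataset@X, steps, step = dataset@grid@step)
  grid <- dataset@grid
  for (s in steps)
    if (s$type == "savgol") grid <- .trimGrid(grid, (s$window - 1L) %/% 2L)
  calibrationDataset(X, dataset@y, dataset@labels, grid)
}

# assemble the sub-replicate-scale dataset of mean raw spectra
.assembleDataset <- function(config) {
  seed <- config$seed
  sim <- config$simulate
  if (is.null(config$input)) {
    design <- .stage("design", buildDesign(sim$season, blocks = sim$blocks))
    traj <- if (!is.null(sim$trajectories)) sim$trajectories
            else defaultTrajectories(sim$season)
    psi <- .stage("reference", simulatePsi(design, traj, seed))
    scfg <- do.call(streamConfig, sim$stream)
    signature <- leafSignature(scfg, psi = config$filter$psi)
    rows <- list()
    .stage("streams", for (d in design@dates)
      for (r in unique(design@layout$replicate_id))
        for (s in sim$side) {
          stream <- simulateStream(design, psi, d, r, scfg, s, seed)
          psiRows <- psi[psi$date == d & psi$replicate_id == r, ]
          rows <- c(rows, .processStream(stream, signature, config$filter,
                                         design, psiRows))
        })
    grid <- spectraGrid(signature)
  } else {
    inp <- config$input
    batch <- .stage("read", if (is(inp$spectra, "SpectraBatch")) inp$spectra
                    else readBatch(inp$spectra))
    psi <- .stage("read", if (is.data.frame(inp$reference)) inp$reference
                  else read.csv(inp$reference, stringsAsFactors = FALSE))
    design <- if (!is.null(inp$design)) inp$design else
      buildDesign(unique(psi$date))
    scfg <- do.call(streamConfig, sim$stream)
    signature <- if (!is.null(inp$signature)) inp$signature
                 else leafSignature(scfg, psi = config$filter$psi,
                                    grid = spectraGrid(batch))
    meta <- spectraMeta(batch)
    keys <- paste(meta$date, meta$replicate_id, meta$side, sep = "|")
    rows <- list()
    .stage("streams", for (k in unique(keys)) {
      sub <- batch[, keys == k]
      m1 <- spectraMeta(sub)[1L, ]
      psiRows <- psi[psi$date == m1$date & psi$replicate_id == m1$replicate_id, ]
      if (!nrow(psiRows)) next
      rows <- c(rows, .processStream(sub, signature, config$filter,
                                     design, psiRows))
    })
    grid <- spectraGrid(batch)
  }
  if (!length(rows)) stop("no usable spectra survived filtering")
  ds <- calibrationDataset(do.call(rbind, lapply(rows, `[[`, "x")),
                           vapply(rows, `[[`, 0, "y"),
                           do.call(rbind, lapply(rows, `[[`, "label")),
                           grid)
  ds[.sampleOrder(ds@labels)]
}

#' Run the full water-status modelling pipeline
#'
#' Executes, in order: stream simulation or loading, signature filtering,
#' positional trimming to the measured middle vines, allocation to
#' sub-replicate units and group averaging, linking with the psi_s
#' references, optional aggregation to the field-replicate scale, spectral
#' preprocessing, PCA-based Q/T-squared outlier removal (single pass, before
#' the split), a stratified 80/20 calibration/external split, venetian-blind
#' and leave-one-day-out cross-validation, latent-variable selection at the
#' minimum venetian CV-RMSE, a refit at the selected complexity, and
#' external prediction.
#'
#' @param config configuration list (see [defaultConfig()]) or the path of
#'   a YAML file
#' @return list with `report` (one-row data.frame of Rc2/RMSEC, venetian and
#'   LODO Rcv2/CV-RMSE, Rp2/RMSEP plus sample accounting), `model` (the
#'   refitted \linkS4class{PLSModel}), `dataset` (clean preprocessed
#'   dataset), `calibration`, `external`, `externalPredictions`, `qc` audit,
#'   `cv` (both error curves) and the expanded `config`
#' @examples
#' \donttest{
#' res <- runPipeline(defaultConfig(seed = 1,
#'   simulate = list(season = "2015", side = "east", blocks = 2L)))
#' res$report
#' }
#' @export
runPipeline <- function(config = defaultConfig()) {
  if (is.character(config)) config <- loadConfig(config)
  config <- utils::modifyList(defaultConfig(), config)
  ds <- .assembleDataset(config)
  nSub <- length(ds)
  if (identical(config$scale, "field_replicate"))
    ds <- .stage("scale", fieldReplicateScale(ds))
  dsP <- .stage("preprocess", .preprocessDataset(ds, config$preprocess))
  qcRes <- .stage("qc", flagAndRemove(dsP, alpha = config$qc$alpha,
                                      varExplained = config$qc$varExplained,
                                      maxComponents = config$qc$maxComponents))
  clean <- qcRes$clean
  sp <- .stage("split", splitCalibration(clean, config$split$fraction,
                                         config$split$strata,
                                         seed = config$seed))
  cal <- sp$calibration
  cvVen <- .stage("cv", crossValidate(cal,
                                      venetianFolds(cal, config$cv$nFolds),
                                      config$cv$maxLV))
  cvLodo <- .stage("cv", tryCatch(crossValidate(cal, lodoFolds(cal),
                                                config$cv$maxLV),
                                  error = function(e) NULL))
  nLV <- selectNLV(cvVen$cvRMSE)
  model <- .stage("refit", plsFit(cal@X, cal@y, nLV,
                                  preprocess = preprocessCode(config$preprocess),
                                  grid = cal@grid))
  fitted <- predictPsi(model, cal)
  mc <- regMetrics(cal@y, fitted)
  ext <- sp$external
  yhatExt <- predictPsi(model, ext)
  mp <- if (length(ext) >= 2L) regMetrics(ext@y, yhatExt)
        else list(R2 = NA_real_, RMSE = NA_real_)
  report <- data.frame(
    side = paste(unique(ds@labels$side), collapse = "&"),
    scale = config$scale,
    preprocess = preprocessCode(config$preprocess),
    n_subunit = nSub, n_scale = length(dsP@y),
    n_removed = length(qcRes$removed),
    removal_pct = removalRate(length(qcRes$removed), length(dsP@y)),
    n_calibration = length(cal), n_external = length(ext), nLV = nLV,
    RMSEC = mc$RMSE, Rc2 = mc$R2,
    CV_RMSE_venetian = cvVen$cvRMSE[nLV], Rcv2_venetian = cvVen$cvR2[nLV],
    CV_RMSE_lodo = if (is.null(cvLodo)) NA_real_ else cvLodo$cvRMSE[nLV],
    Rcv2_lodo = if (is.null(cvLodo)) NA_real_ else cvLodo$cvR2[nLV],
    RMSEP = mp$RMSE, Rp2 = mp$R2)
  out <- list(report = report, model = model, dataset = clean,
              calibration = cal, external = ext,
              externalPredictions = data.frame(ext@labels, psi = ext@y,
                                               psi_pred = yhatExt),
              qc = qcRes$audit, qcModelSize = length(qcRes$audit$Q),
              cv = list(venetian = cvVen, lodo = cvLodo),
              config = config)
  if (!is.null(config$outdir)) .persistRun(out, config$outdir)
  out
}

.persistRun <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(out$report, file.path(dir, "report.csv"), row.names = FALSE)
  write.csv(out$qc, file.path(dir, "qc_audit.csv"), row.names = FALSE)
  write.csv(out$cv$venetian, file.path(dir, "cv_venetian.csv"),
            row.names = FALSE)
  if (!is.null(out$cv$lodo))
    write.csv(out$cv$lodo, file.path(dir, "cv_lodo.csv"), row.names = FALSE)
  write.csv(out$externalPredictions,
            file.path(dir, "external_predictions.csv"), row.names = FALSE)
  write.csv(data.frame(out$dataset@labels, psi = out$dataset@y),
            file.path(dir, "samples.csv"), row.names = FALSE)
  writePLSModel(out$model, file.path(dir, "model.json"))
  invisible(dir)
}
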