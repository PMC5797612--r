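# canonical acquisition-like ordering used before venetian-blind folding
.sampleOrder <- function(labels) {
  order(labels$date, labels$side, labels$replicate_id, labels$sub_unit)
}

#' Split a dataset into calibration and external validation sets
#'
#' Pseudorandom stratified split: within each stratum (default date x
#' treatment x side) a rounded share of `1 - fraction` samples is drawn into
#' the external set. Strata with fewer than two samples go wholly to
#' calibration with a warning. Reproducible for a fixed seed.
#'
#' @param dataset a \linkS4class{CalibrationDataset}
#' @param fraction calibration fraction in (0, 1), default 0.80
#' @param strata label columns defining the strata
#' @param seed integer seed
#' @return list with `calibration` and `external` datasets
#' @export
splitCalibration <- function(dataset, fraction = 0.8,
                             strata = c("date", "treatment", "side"),
                             seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- length(dataset)
  if (!n) stop("empty dataset")
  strata <- intersect(strata, colnames(dataset@labels))
  key <- if (length(strata))
    do.call(paste, c(dataset@labels[, strata, drop = FALSE], sep = "|"))
  else rep("all", n)
  ext <- logical(n)
  .withSeed(.subSeed(seed, "split"), {
    for (g in unique(key)) {
      idx <- which(key == g)
      if (length(idx) < 2L) {
        warning("stratum '", g, "' has fewer than 2 samples; ",
                "assigned to calibration")
        next
      }
      k <- round((1 - fraction) * length(idx))
      if (k > 0L) ext[sample(idx, k)] <- TRUE
    }
  })
  list(calibration = dataset[!ext], external = dataset[ext])
}

#' Venetian-blind fold assignment
#'
#' Sample at (1-based) position `k` of the ordered dataset goes to fold
#' `((k - 1) mod nFolds) + 1`, i.e. fold i collects samples i, i + n,
#' i + 2n, ... Samples should be ordered by (date, side, replicate,
#' sub-unit) so folds interleave dates and conditions.
#'
#' @param n number of samples (or a \linkS4class{CalibrationDataset}, whose
#'   canonical ordering is then used)
#' @param nFolds number of folds (2..n)
#' @return integer vector of fold indices in 1..nFolds
#' @export
venetianFolds <- function(n, nFolds = 10L) {
  if (is(n, "CalibrationDataset")) n <- length(n)
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L) stop("need at least two folds")
  if (nFolds > n) stop("more folds than samples")
  ((seq_len(n) - 1L) %% nFolds) + 1L
}

#' Leave-one-day-out fold assignment
#'
#' One fold per distinct measurement date; each fold holds out every sample
#' of that date.
#'
#' @param dates per-sample date labels (or a \linkS4class{CalibrationDataset})
#' @return integer vector of fold indices (1..number of distinct dates,
#'   dates in sorted order)
#' @export
lodoFolds <- function(dates) {
  if (is(dates, "CalibrationDataset")) dates <- dates@labels$date
  u <- sort(unique(dates))
  if (length(u) < 2L) stop("leave-one-day-out needs at least two dates")
  match(dates, u)
}

#' Cross-validated error curve over latent variables
#'
#' For each fold, fits NIPALS PLS on the remaining samples (centring refit
#' inside the training fold, so no information leaks from the held-out
#' fold) and predicts the fold at every latent-variable count; predictions
#' are pooled over folds and scored once per count.
#'
#' @param dataset a \linkS4class{CalibrationDataset} (already preprocessed;
#'   SNV/derivative act per spectrum and carry no training state)
#' @param folds integer fold assignment (see [venetianFolds()],
#'   [lodoFolds()])
#' @param maxLV largest latent-variable count to test; silently capped at
#'   what the smallest training fold supports
#' @return data.frame with columns `lv`, `cvRMSE`, `cvR2`
#' @export
crossValidate <- function(dataset, folds, maxLV = 15L) {
  n <- length(dataset)
  if (length(folds) != n) stop("fold assignment does not match the dataset")
  ids <- sort(unique(folds))
  if (any(tabulate(match(folds, ids)) < 1L)) stop("empty fold")
  minTrain <- n - max(tabulate(match(folds, ids)))
  maxLV <- min(as.integer(maxLV), minTrain - 1L, ncol(dataset@X))
  if (maxLV < 1L) stop("training folds too small for even one latent variable")
  pred <- matrix(NA_real_, n, maxLV)
  for (f in ids) {
    test <- folds == f
    nip <- .nipals(dataset@X[!test, , drop = FALSE], dataset@y[!test], maxLV)
    Xt <- sweep(dataset@X[test, , drop = FALSE], 2L, nip$xMean)
    for (a in seq_len(maxLV)) {
      # if the training fold ran out of rank, reuse the deepest available fit
      aEff <- min(a, nip$a)
      B <- .plsCoef(nip$W, nip$P, nip$q, aEff)
      pred[test, a] <- nip$yMean + Xt %*% B
    }
  }
  out <- do.call(rbind, lapply(seq_len(maxLV), function(a) {
    m <- regMetrics(dataset@y, pred[, a])
    data.frame(lv = a, cvRMSE = m$RMSE, cvR2 = m$R2)
  }))
  out
}

#' Balanced east & west dataset
#'
#' Builds a two-side dataset the size of a single side: for every
#' (treatment, date) cell, half the cell's samples (+/- 1, alternating by
#' cell so neither side is systematically favoured) are drawn
#' pseudorandomly from the east dataset and the rest from the west.
#'
#' @param east,west \linkS4class{CalibrationDataset} objects sharing dates
#'   and treatments
#' @param seed integer seed
#' @return a merged \linkS4class{CalibrationDataset}
#' @export
balancedMerge <- function(east, west, seed = 1L) {
  keyE <- paste(east@labels$treatment, east@labels$date, sep = "|")
  keyW <- paste(west@labels$treatment, west@labels$date, sep = "|")
  cells <- sort(unique(keyE))
  if (!setequal(cells, unique(keyW)))
    stop("east and west do not share the same (treatment, date) cells")
  pick <- .withSeed(.subSeed(seed, "merge"), {
    takeE <- integer(); takeW <- integer()
    for (ci in seq_along(cells)) {
      iE <- which(keyE == cells[ci]); iW <- which(keyW == cells[ci])
      if (!length(iE) || !length(iW))
        stop("empty cell on one side: ", cells[ci])
      k <- length(iE)
      kE <- if (ci %% 2L) ceiling(k / 2) else floor(k / 2)
      kW <- k - kE
      if (kE > length(iE) || kW > length(iW))
        stop("cell ", cells[ci], " too small on one side for a balanced draw")
      takeE <- c(takeE, sample(iE, kE))
      takeW <- c(takeW, sample(iW, kW))
    }
    list(E = sort(takeE), W = sort(takeW))
  })
  subE <- east[pick$E]; subW <- west[pick$W]
  merged <- calibrationDataset(rbind(subE@X, subW@X), c(subE@y, subW@y),
                               rbind(subE@labels, subW@labels), east@grid)
  merged[.sampleOrder(merged@labels)]
}

#' Aggregate a dataset to the field-replicate scale
#'
#' Averages the three sub-replicate mean spectra and their psi_s values per
#' (date, side, replicate), producing the coarser dataset the field
#' replicate models are trained on.
#'
#' @param dataset sub-replicate-scale \linkS4class{CalibrationDataset}
#' @return a \linkS4class{CalibrationDataset} with one sample per replicate
#'   and date
#' @export
fieldReplicateScale <- function(dataset) {
  lb <- dataset@labels
  key <- paste(lb$date, lb$side, lb$replicate_id, sep = "|")
  groups <- split(seq_along(key), key)
  groups <- groups[order(vapply(groups, min, 0L))]
  X <- do.call(rbind, lapply(groups, function(i)
    colMeans(dataset@X[i, , drop = FALSE])))
  y <- vapply(groups, function(i) mean(dataset@y[i]), 0)
  labels <- do.call(rbind, lapply(groups, function(i) {
    out <- lb[i[1L], , drop = FALSE]
    out$sub_unit <- NA
    out$x <- mean(lb$x[i]); out$y <- mean(lb$y[i])
    out
  }))
  rownames(labels) <- NULL
  calibrationDataset(X, y, labels, dataset@grid)
}
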