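#' Construct a calibration dataset
#'
#' @param X samples x channels matrix of (mean) spectra
#' @param y stem water potential references (MPa, negative)
#' @param labels data.frame of per-sample labels (date, side, treatment,
#'   replicate_id, sub_unit, x, y); missing columns are filled with `NA`
#' @param grid the \linkS4class{WavelengthGrid} of the columns of `X`
#' @return a \linkS4class{CalibrationDataset}
#' @export
calibrationDataset <- function(X, y, labels = NULL, grid) {
  X <- as.matrix(X)
  if (is.null(labels)) labels <- data.frame(row.names = seq_len(nrow(X)))
  labels <- as.data.frame(labels)
  for (col in c("date", "side", "treatment", "replicate_id", "sub_unit",
                "x", "y"))
    if (!col %in% colnames(labels)) labels[[col]] <- rep(NA, nrow(X))
  new("CalibrationDataset", X = X, y = as.numeric(y), labels = labels,
      grid = grid)
}

#' @describeIn calibrationDataset subset samples
#' @param x a CalibrationDataset
#' @param i sample index (integer or logical)
#' @export
setMethod("[", "CalibrationDataset", function(x, i, j, ..., drop = FALSE) {
  new("CalibrationDataset", X = x@X[i, , drop = FALSE], y = x@y[i],
      labels = x@labels[i, , drop = FALSE], grid = x@grid)
})

setMethod("show", "CalibrationDataset", function(object) {
  cat(sprintf("CalibrationDataset: %d samples x %d channels, psi %.2f..%.2f MPa\n",
              nrow(object@X), ncol(object@X),
              if (length(object@y)) min(object@y) else NA,
              if (length(object@y)) max(object@y) else NA))
})

#' @describeIn calibrationDataset number of samples
#' @export
setMethod("length", "CalibrationDataset", function(x) length(x@y))

#' Fit a NIPALS PLS1 regression
#'
#' Mean-centred (not variance-scaled) partial least squares with a single
#' response. For PLS1 each latent variable is closed-form: weight
#' `w = X'y / |X'y|`, score `t = X w`, X-loading `p = X't / t't`, y-loading
#' `q = y't / t't`, then X is deflated by `t p'`. Regression coefficients
#' are `B = W (P'W)^{-1} q`, so predictions are
#' `yhat = ymean + (x - xmean) B`.
#'
#' @param X samples x channels matrix
#' @param y response vector (length `nrow(X)`, non-constant)
#' @param nLV number of latent variables (at most `min(n - 1, channels)`)
#' @param preprocess shorthand recorded on the model (informational)
#' @param grid wavelength grid of the channels; a unit index grid is used
#'   when omitted
#' @return a \linkS4class{PLSModel} with `nLV` latent variables
#' @export
plsFit <- function(X, y, nLV, preprocess = "", grid = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least two samples")
  if (length(y) != n) stop("X and y disagree on the sample count")
  if (var(y) == 0) stop("zero-variance response")
  nLV <- as.integer(nLV)
  if (nLV < 1L || nLV > min(n - 1L, ncol(X)))
    stop("nLV must be in 1..min(n - 1, channels)")
  if (is.null(grid)) grid <- makeGrid(1, ncol(X), 1)
  nip <- .nipals(X, y, nLV)
  if (nip$a < nLV)
    stop("X rank exhausted after ", nip$a, " latent variables")
  B <- .plsCoef(nip$W, nip$P, nip$q, nLV)
  new("PLSModel", xMean = nip$xMean, yMean = nip$yMean, W = nip$W,
      P = nip$P, q = nip$q, coefficients = as.numeric(B), nLV = nLV,
      preprocess = preprocess, grid = grid)
}

# NIPALS PLS1 core; stops early (a < maxLV) when X is rank-exhausted
.nipals <- function(X, y, maxLV) {
  xMean <- colMeans(X)
  yMean <- mean(y)
  Xc <- sweep(X, 2L, xMean)
  yc <- y - yMean
  W <- P <- matrix(0, ncol(X), maxLV)
  q <- numeric(maxLV)
  a <- 0L
  for (k in seq_len(maxLV)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt < 1e-28) break
    P[, k] <- crossprod(Xc, t) / tt
    q[k] <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(P[, k])
    yc <- yc - q[k] * t
    W[, k] <- w
    a <- k
  }
  list(xMean = xMean, yMean = yMean, W = W, P = P, q = q, a = a)
}

.plsCoef <- function(W, P, q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
}

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d latent variables (of %d fitted), %d channels%s\n",
              object@nLV, ncol(object@W), length(object@xMean),
              if (nzchar(object@preprocess))
                paste0(", preprocess ", object@preprocess) else ""))
})

#' Predict stem water potential from spectra
#'
#' Linear prediction `yhat = ymean + (x - xmean) B` at any complexity up to
#' the fitted latent-variable count.
#'
#' @param model a \linkS4class{PLSModel}
#' @param X samples x channels matrix, numeric vector (one spectrum), or
#'   \linkS4class{CalibrationDataset}
#' @param nLV latent variables to use (default: the model's selection)
#' @return numeric vector of predictions (MPa)
#' @export
predictPsi <- function(model, X, nLV = model@nLV) {
  if (is(X, "CalibrationDataset")) X <- X@X
  if (is.null(dim(X))) X <- matrix(X, 1L)
  X <- as.matrix(X)
  if (ncol(X) != length(model@xMean))
    stop("channel count does not match the model")
  nLV <- as.integer(nLV)
  if (nLV < 1L || nLV > ncol(model@W))
    stop("nLV outside the fitted range")
  B <- if (nLV == model@nLV) model@coefficients
       else as.numeric(.plsCoef(model@W, model@P, model@q, nLV))
  as.numeric(model@yMean + sweep(X, 2L, model@xMean) %*% B)
}

#' Regression quality metrics
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`; `R2 = 1 - SS_res / SS_tot` with the
#' total sum of squares taken about the evaluation set's own mean.
#'
#' @param y observed values
#' @param yhat predicted values (same length, n >= 2)
#' @return named list with `R2` and `RMSE`
#' @examples
#' regMetrics(c(0, 1, 2), c(0, 1, 1))  # RMSE sqrt(1/3), R2 0.5
#' @export
regMetrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2L) stop("need at least two observations")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R2 undefined for a constant evaluation set")
  list(R2 = 1 - sum((y - yhat)^2) / sst,
       RMSE = sqrt(mean((y - yhat)^2)))
}

#' Select the latent-variable count
#'
#' Argmin of the cross-validated RMSE curve; ties break toward fewer latent
#' variables.
#'
#' @param cvRMSE numeric vector, element a = CV-RMSE with a latent variables
#' @return the selected count (integer)
#' @examples
#' selectNLV(c(0.30, 0.20, 0.25))  # 2
#' @export
selectNLV <- function(cvRMSE) {
  if (!length(cvRMSE)) stop("empty CV-RMSE curve")
  which.min(cvRMSE)
}

#' Serialize / restore a PLS model as JSON
#'
#' @param model a \linkS4class{PLSModel}
#' @param path output file
#' @return `writePLSModel` returns `path` invisibly; `readPLSModel` the model
#' @export
writePLSModel <- function(model, path) {
  obj <- list(xMean = model@xMean, yMean = model@yMean,
              W = model@W, P = model@P, q = model@q,
              coefficients = model@coefficients, nLV = model@nLV,
              preprocess = model@preprocess,
              grid = c(model@grid@start, model@grid@stop, model@grid@step))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePLSModel
#' @export
readPLSModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PLSModel", xMean = o$xMean, yMean = o$yMean,
      W = as.matrix(o$W), P = as.matrix(o$P), q = o$q,
      coefficients = o$coefficients, nLV = as.integer(o$nLV),
      preprocess = o$preprocess,
      grid = makeGrid(o$grid[1L], o$grid[2L], o$grid[3L]))
}
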