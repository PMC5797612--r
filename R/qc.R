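#' Fit a PCA model for spectral QC
#'
#' Mean-centred PCA via singular value decomposition. The component count
#' `p` defaults to the smallest number capturing at least `varExplained` of
#' the variance, capped at `maxComponents` (and at `n - 1`). Component signs
#' are fixed so each loading's largest-magnitude element is positive, making
#' the fit bitwise reproducible.
#'
#' @param X samples x channels matrix (preprocessed spectra)
#' @param p number of components; `NULL` selects by explained variance
#' @param alpha confidence level for the control limits (default 0.95)
#' @param varExplained cumulative variance target used when `p` is `NULL`
#' @param maxComponents cap on the automatic component count (default 10)
#' @return a \linkS4class{PCAModel}
#' @export
pcaFit <- function(X, p = NULL, alpha = 0.95, varExplained = 0.95,
                   maxComponents = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least two samples")
  if (!is.null(p) && p >= n) stop("p must be smaller than the sample count")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  lambda <- sv$d^2 / (n - 1)
  rank <- sum(sv$d > sv$d[1L] * 1e-12)
  if (is.null(p)) {
    cum <- cumsum(lambda[seq_len(rank)]) / sum(lambda[seq_len(rank)])
    p <- min(which(cum >= varExplained)[1L], maxComponents, rank, n - 1L)
  }
  p <- as.integer(p)
  if (p < 1L || p > rank) stop("p must be in 1..rank(X)")
  L <- t(sv$v[, seq_len(p), drop = FALSE])  # p x channels
  for (k in seq_len(p)) {
    j <- which.max(abs(L[k, ]))
    if (L[k, j] < 0) L[k, ] <- -L[k, ]
  }
  model <- new("PCAModel", center = ctr, loadings = L,
               eigenvalues = lambda[seq_len(rank)], n = as.integer(n),
               p = p, alpha = alpha, trainingQ = numeric())
  model@trainingQ <- scoresQT2(model, X)@Q
  model
}

setMethod("show", "PCAModel", function(object) {
  ev <- object@eigenvalues
  cat(sprintf("PCAModel: %d components (of rank %d), n = %d, %.1f%% variance\n",
              object@p, length(ev), object@n,
              100 * sum(ev[seq_len(object@p)]) / sum(ev)))
})

#' Q residuals and Hotelling T-squared for new spectra
#'
#' Scores are `t = (x - center) L'`; `Q` is the squared norm of the
#' off-model residual `(x - center) - t L`; `T2 = sum_k t_k^2 / lambda_k`
#' with `lambda_k` the training score variance of component k.
#'
#' @param model a \linkS4class{PCAModel}
#' @param X samples x channels matrix on the model's channel space
#' @return a \linkS4class{QCResult} with infinite limits (see
#'   [flagAndRemove()] for limit-based removal)
#' @export
scoresQT2 <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model@center))
    stop("channel count does not match the PCA model")
  Xc <- sweep(X, 2L, model@center)
  Tsc <- Xc %*% t(model@loadings)
  resid <- Xc - Tsc %*% model@loadings
  Q <- unname(rowSums(resid^2))
  T2 <- unname(rowSums(sweep(Tsc^2, 2L,
                             model@eigenvalues[seq_len(model@p)], `/`)))
  new("QCResult", Q = Q, T2 = T2, Qlimit = Inf, T2limit = Inf,
      outlier = rep(FALSE, nrow(X)))
}

setMethod("show", "QCResult", function(object) {
  cat(sprintf("QCResult: %d samples, %d flagged (Q limit %.4g, T2 limit %.4g)\n",
              length(object@Q), sum(object@outlier), object@Qlimit,
              object@T2limit))
})

#' Hotelling T-squared control limit
#'
#' The F-based bound `T2 = p (n - 1) / (n - p) * F_{p, n-p, alpha}` for `p`
#' retained components fitted on `n` samples.
#'
#' @param p number of PC scores considered
#' @param n training sample count (must exceed `p`)
#' @param alpha confidence level in (0, 1)
#' @return the T-squared limit
#' @examples
#' hotellingLimit(2, 100, 0.95)
#' @export
hotellingLimit <- function(p, n, alpha = 0.95) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (p < 1) stop("p must be at least 1")
  if (n <= p) stop("need n > p for the F-based limit")
  p * (n - 1) / (n - p) * qf(alpha, p, n - p)
}

#' Q-residual control limit
#'
#' Jackson-Mudholkar approximation from the moments of the discarded
#' eigenvalues. When the residual spectrum is (numerically) empty the limit
#' is 0; when the moment expression degenerates the empirical `alpha`
#' quantile of the training Q values is used instead.
#'
#' @param model a \linkS4class{PCAModel}
#' @param alpha confidence level (defaults to the model's)
#' @return the Q limit
#' @export
qLimit <- function(model, alpha = model@alpha) {
  ev <- model@eigenvalues
  resid <- ev[-seq_len(model@p)]
  tol <- if (length(ev)) ev[1L] * 1e-12 else 0
  resid <- resid[resid > tol]
  if (!length(resid)) return(0)
  th1 <- sum(resid); th2 <- sum(resid^2); th3 <- sum(resid^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  fallback <- function() unname(quantile(model@trainingQ, alpha, type = 7))
  if (!is.finite(h0) || h0 <= 0) return(fallback())
  z <- qnorm(alpha)
  inner <- z * sqrt(2 * th2 * h0^2) / th1 + 1 + th2 * h0 * (h0 - 1) / th1^2
  if (!is.finite(inner) || inner <= 0) return(fallback())
  th1 * inner^(1 / h0)
}

#' Flag and remove atypical spectra
#'
#' Computes Q and T-squared for every sample of the dataset under the given
#' PCA model and removes those exceeding either control limit (single pass).
#'
#' @param dataset a \linkS4class{CalibrationDataset} (preprocessed)
#' @param model a \linkS4class{PCAModel}; fitted on `dataset@X` when `NULL`
#' @param alpha confidence level for both limits
#' @param ... passed to [pcaFit()] when `model` is `NULL`
#' @return list with `clean` (dataset without outliers), `removed` (integer
#'   indices), `qc` (the full \linkS4class{QCResult}) and `audit`, a
#'   data.frame (sample, Q, T2, Q_limit, T2_limit, removed) mirroring the
#'   QC audit CSV
#' @export
flagAndRemove <- function(dataset, model = NULL, alpha = 0.95, ...) {
  if (is.null(model)) model <- pcaFit(dataset@X, alpha = alpha, ...)
  qc <- scoresQT2(model, dataset@X)
  qlim <- qLimit(model, alpha)
  tlim <- hotellingLimit(model@p, model@n, alpha)
  mask <- qc@Q > qlim | qc@T2 > tlim
  qc <- new("QCResult", Q = qc@Q, T2 = qc@T2, Qlimit = qlim,
            T2limit = tlim, outlier = mask)
  audit <- data.frame(sample = seq_along(mask), Q = qc@Q, T2 = qc@T2,
                      Q_limit = qlim, T2_limit = tlim, removed = mask)
  list(clean = dataset[!mask], removed = which(mask), qc = qc, audit = audit)
}

#' Percentage of samples removed
#'
#' @param removed number of removed samples
#' @param total total sample count
#' @return percentage (0-100)
#' @examples
#' removalRate(32, 324)  # ~9.9
#' @export
removalRate <- function(removed, total) 100 * removed / total
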