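.snvMatrix <- function(X) {
  mu <- rowMeans(X)
  s <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1L))
  if (any(s <= 0))
    stop("degenerate input: constant spectrum has no SNV transform")
  (X - mu) / s
}

#' @rdname snv
#' @export
setMethod("snv", "numeric", function(x)
  as.numeric(.snvMatrix(matrix(x, 1L))))

#' @rdname snv
#' @export
setMethod("snv", "matrix", function(x) .snvMatrix(x))

#' @rdname snv
#' @export
setMethod("snv", "SpectraBatch", function(x) {
  a <- t(.snvMatrix(t(absorbance(x))))
  SpectraBatch(a, spectraGrid(x), spectraMeta(x))
})

# central Savitzky-Golay convolution coefficients: least-squares fit of a
# polynomial of order `polyorder` on the window, derivative `deriv` at centre
.savgolCoef <- function(window, polyorder, deriv) {
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("Savitzky-Golay window must be odd")
  if (polyorder >= window) stop("window must exceed the polynomial order")
  if (deriv > polyorder) stop("derivative order must not exceed polyorder")
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:polyorder, `^`)
  C <- solve(crossprod(A), t(A))
  C[deriv + 1L, ] * factorial(deriv)
}

.savgolMatrix <- function(X, window, polyorder, deriv, step) {
  p <- ncol(X)
  if (window > p) stop("window exceeds the number of channels")
  coef <- .savgolCoef(window, polyorder, deriv) / step^deriv
  nOut <- p - window + 1L
  out <- matrix(0, nrow(X), nOut)
  for (k in seq_len(window))
    out <- out + coef[k] * X[, k:(k + nOut - 1L), drop = FALSE]
  out
}

#' @rdname savgol
#' @export
setMethod("savgol", "numeric", function(x, window, polyorder = 2L,
                                        deriv = 0L, step = 1)
  as.numeric(.savgolMatrix(matrix(x, 1L), window, polyorder, deriv, step)))

#' @rdname savgol
#' @export
setMethod("savgol", "matrix", function(x, window, polyorder = 2L,
                                       deriv = 0L, step = 1)
  .savgolMatrix(x, window, polyorder, deriv, step))

#' @rdname savgol
#' @export
setMethod("savgol", "SpectraBatch", function(x, window, polyorder = 2L,
                                             deriv = 0L, step = 1) {
  g <- spectraGrid(x)
  a <- t(.savgolMatrix(t(absorbance(x)), window, polyorder, deriv, g@step))
  SpectraBatch(a, .trimGrid(g, (window - 1L) %/% 2L), spectraMeta(x))
})

#' Parse / print preprocessing shorthand
#'
#' Shorthand codes follow chemometric convention: steps joined by `+`,
#' applied left to right; `SNV` is the standard normal variate and `D<d>W<w>`
#' a Savitzky-Golay derivative of order `d` with a `w`-channel window
#' (polynomial order 2). `""` is the identity.
#'
#' @param code e.g. `"SNV+D1W15"`, `"D1W7"`, `""`
#' @return `parsePreprocess`: a list of step descriptors; `preprocessCode`:
#'   the shorthand for a step list
#' @export
parsePreprocess <- function(code) {
  if (is.list(code)) return(code)
  if (!nzchar(code)) return(list())
  parts <- strsplit(code, "+", fixed = TRUE)[[1L]]
  lapply(parts, function(p) {
    if (toupper(p) == "SNV") return(list(type = "snv"))
    m <- regmatches(p, regexec("^D([0-9]+)W([0-9]+)$", p, ignore.case = TRUE))[[1L]]
    if (length(m) == 3L)
      return(list(type = "savgol", window = as.integer(m[3L]),
                  polyorder = 2L, deriv = as.integer(m[2L])))
    stop("unknown preprocessing step: ", p)
  })
}

#' @rdname parsePreprocess
#' @param steps a step list as returned by `parsePreprocess`
#' @export
preprocessCode <- function(steps) {
  if (is.character(steps)) return(steps)
  if (!length(steps)) return("")
  paste(vapply(steps, function(s) switch(s$type,
    snv = "SNV",
    savgol = sprintf("D%dW%d", s$deriv, s$window),
    stop("unknown step type: ", s$type)), ""), collapse = "+")
}

#' Apply a preprocessing pipeline
#'
#' Applies the steps of a shorthand code (or step list) left to right.
#' Savitzky-Golay steps shrink the wavelength axis by `window - 1` channels;
#' matrix input must supply the grid `step` so derivatives come out per nm.
#'
#' @param x samples x channels matrix, numeric vector, or
#'   \linkS4class{SpectraBatch}
#' @param cfg shorthand code or [parsePreprocess()] list
#' @param step channel spacing in nm (ignored for SpectraBatch input)
#' @return preprocessed object of the same kind as `x`
#' @examples
#' g <- makeGrid()
#' x <- sin(wavelengths(g) / 200)
#' length(applyPreprocess(x, "SNV+D1W15", step = 4))  # 237
#' @export
applyPreprocess <- function(x, cfg, step = 1) {
  steps <- parsePreprocess(cfg)
  for (s in steps) {
    x <- switch(s$type,
      snv = snv(x),
      savgol = if (is(x, "SpectraBatch"))
        savgol(x, s$window, s$polyorder, s$deriv)
      else savgol(x, s$window, s$polyorder, s$deriv, step))
  }
  x
}

#' Reference leaf signature spectrum
#'
#' The noise-free leaf archetype of the stream generator (baseline 0,
#' scatter 1) at a given stem water potential: the static, well-taken leaf
#' spectrum against which on-the-go spectra are compared during filtering.
#'
#' @param cfg a [streamConfig()]
#' @param psi stem water potential of the archetype leaf (MPa)
#' @param grid wavelength grid
#' @return a single-spectrum \linkS4class{SpectraBatch} tagged `leaf`
#' @export
leafSignature <- function(cfg = streamConfig(), psi = -1.0,
                          grid = makeGrid()) {
  wl <- wavelengths(grid)
  a <- .leafMatrix(wl) + (cfg$alpha0 + cfg$alpha1 * psi) *
    .waterBands(wl, cfg$bandCenters, cfg$bandWidths)
  SpectraBatch(a, grid, data.frame(class_tag = "leaf"))
}

#' Signature-spectrum contaminant filter
#'
#' Retains spectra that look like the supplied leaf signature: Pearson
#' correlation with the signature at least `threshold` (correlation is
#' computed on centred/scaled spectra, so SNV-normalising first is implied)
#' and mean absorbance within the gates. Everything else (gaps, wood, metal,
#' saturated shots) is returned in the rejected batch; the partition is
#' exhaustive.
#'
#' @param batch a \linkS4class{SpectraBatch} of raw spectra
#' @param signature single-spectrum SpectraBatch or numeric vector on the
#'   same grid
#' @param threshold correlation threshold in \[-1, 1\] (default 0.90)
#' @param gates length-2 numeric: admissible range of the per-spectrum mean
#'   absorbance
#' @return list with elements `retained`, `rejected` (both SpectraBatch)
#'   and the logical `mask`
#' @export
signatureFilter <- function(batch, signature, threshold = 0.90,
                            gates = c(0.05, 2.5)) {
  if (threshold < -1 || threshold > 1)
    stop("threshold must be a correlation in [-1, 1]")
  sig <- if (is(signature, "SpectraBatch")) {
    if (!isTRUE(all.equal(wavelengths(spectraGrid(signature)),
                          wavelengths(spectraGrid(batch)))))
      stop("signature and batch are on different wavelength grids")
    as.numeric(absorbance(signature)[, 1L])
  } else as.numeric(signature)
  if (length(sig) != nChannels(spectraGrid(batch)))
    stop("signature length does not match the batch grid")
  A <- absorbance(batch)
  mu <- colMeans(A)
  Ac <- A - rep(mu, each = nrow(A))
  ss <- sqrt(colSums(Ac^2))
  sc <- sig - mean(sig)
  r <- ifelse(ss > 0, colSums(Ac * sc) / (ss * sqrt(sum(sc^2))), 0)
  mask <- r >= threshold & mu >= gates[1L] & mu <= gates[2L]
  list(retained = batch[, mask, drop = FALSE],
       rejected = batch[, !mask, drop = FALSE],
       mask = mask)
}
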