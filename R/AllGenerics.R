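#' @rdname WavelengthGrid-class
#' @param x a WavelengthGrid (or object carrying one)
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname WavelengthGrid-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname SpectraBatch-class
#' @param x a SpectraBatch
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname SpectraBatch-class
#' @export
setGeneric("spectraGrid", function(x) standardGeneric("spectraGrid"))

#' @rdname SpectraBatch-class
#' @export
setGeneric("spectraMeta", function(x) standardGeneric("spectraMeta"))

#' @rdname SpectraBatch-class
#' @export
setGeneric("nSpectra", function(x) standardGeneric("nSpectra"))

#' Standard normal variate transform
#'
#' Centres and scales each spectrum to mean 0 and sample standard deviation
#' (n - 1 denominator) 1, removing additive baseline offsets and
#' multiplicative scatter.
#'
#' @param x a numeric vector, a samples x channels matrix, or a
#'   \linkS4class{SpectraBatch}
#' @return an object of the same shape as `x`
#' @export
setGeneric("snv", function(x) standardGeneric("snv"))

#' Savitzky-Golay smoothing / derivative
#'
#' Local least-squares polynomial convolution. Derivatives are scaled by the
#' grid step, i.e. returned per nanometre. Edge channels where the window
#' does not fit are dropped, so the output has `window - 1` fewer channels.
#'
#' @param x a numeric vector, a samples x channels matrix, or a
#'   \linkS4class{SpectraBatch}
#' @param window odd window length in channels (> polyorder)
#' @param polyorder polynomial order of the local fit (default 2)
#' @param deriv derivative order (<= polyorder; 0 = smoothing)
#' @param step channel spacing used to scale derivatives; taken from the
#'   grid for SpectraBatch input
#' @return same shape as `x`, trimmed at both ends
#' @export
setGeneric("savgol", function(x, window, polyorder = 2L, deriv = 0L,
                              step = 1) standardGeneric("savgol"))
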