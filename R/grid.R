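#' Construct a wavelength grid
#'
#' @param start first wavelength (nm)
#' @param stop last wavelength (nm); must exceed `start` and
#'   `(stop - start)` must be divisible by `step`
#' @param step channel spacing (nm)
#' @return a \linkS4class{WavelengthGrid}
#' @examples
#' nChannels(makeGrid(1100, 2100, 4))  # 251
#' @export
makeGrid <- function(start = 1100, stop = 2100, step = 4) {
  new("WavelengthGrid", start = as.numeric(start), stop = as.numeric(stop),
      step = as.numeric(step))
}

#' @rdname WavelengthGrid-class
#' @export
setMethod("wavelengths", "WavelengthGrid", function(x)
  seq(x@start, x@stop, by = x@step))

#' @rdname WavelengthGrid-class
#' @export
setMethod("nChannels", "WavelengthGrid", function(x)
  as.integer(round((x@stop - x@start) / x@step)) + 1L)

setMethod("show", "WavelengthGrid", function(object) {
  cat(sprintf("WavelengthGrid: %g-%g nm, step %g nm (%d channels)\n",
              object@start, object@stop, object@step, nChannels(object)))
})

# grid after dropping k channels at each end (Savitzky-Golay trimming)
.trimGrid <- function(grid, k) {
  makeGrid(grid@start + k * grid@step, grid@stop - k * grid@step, grid@step)
}
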