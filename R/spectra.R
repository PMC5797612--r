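#' Build a SpectraBatch
#'
#' @param absorbance numeric matrix with one column per spectrum and one row
#'   per wavelength channel (a vector is taken as a single spectrum)
#' @param grid the shared \linkS4class{WavelengthGrid}
#' @param meta optional data.frame of per-spectrum metadata; recognised
#'   columns are `date`, `side`, `replicate_id`, `sub_unit`, `timestamp`,
#'   `class_tag`, `position_m`; missing ones are filled with `NA`
#' @return a \linkS4class{SpectraBatch}
#' @examples
#' g <- makeGrid(1100, 2100, 4)
#' b <- SpectraBatch(matrix(rnorm(251 * 3), 251), g)
#' nSpectra(b)
#' @export
SpectraBatch <- function(absorbance, grid, meta = NULL) {
  if (is.null(dim(absorbance))) absorbance <- matrix(absorbance, ncol = 1L)
  absorbance <- as.matrix(absorbance)
  n <- ncol(absorbance)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))
  meta <- as.data.frame(meta)
  if (nrow(meta) == 1L && n > 1L) meta <- meta[rep(1L, n), , drop = FALSE]
  if (nrow(meta) != n)
    stop("metadata must have one row per spectrum")
  for (col in .metaColumns)
    if (!col %in% colnames(meta)) meta[[col]] <- rep(NA, n)
  rownames(absorbance) <- sprintf("a%g", wavelengths(grid))
  colnames(absorbance) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = absorbance),
    colData = S4Vectors::DataFrame(meta[, .metaColumns, drop = FALSE]),
    metadata = list(grid = grid))
  new("SpectraBatch", se)
}

#' @rdname SpectraBatch-class
#' @export
setMethod("absorbance", "SpectraBatch", function(x)
  SummarizedExperiment::assay(x, "absorbance"))

#' @rdname SpectraBatch-class
#' @export
setMethod("spectraGrid", "SpectraBatch", function(x)
  S4Vectors::metadata(x)$grid)

#' @rdname SpectraBatch-class
#' @export
setMethod("spectraMeta", "SpectraBatch", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname SpectraBatch-class
#' @export
setMethod("nSpectra", "SpectraBatch", function(x) ncol(x))

setMethod("show", "SpectraBatch", function(object) {
  g <- spectraGrid(object)
  cat(sprintf("SpectraBatch: %d spectra, %d channels (%g-%g nm, step %g)\n",
              ncol(object), nChannels(g), g@start, g@stop, g@step))
  tags <- spectraMeta(object)$class_tag
  if (any(!is.na(tags))) {
    tb <- table(tags, useNA = "no")
    cat("  class tags:", paste(sprintf("%s=%d", names(tb), tb),
                               collapse = ", "), "\n")
  }
})

#' Allocate a spectral stream to sub-replicate units
#'
#' Splits an acquisition-ordered stream into `nGroups` contiguous,
#' order-preserving groups of near-equal size (sizes differ by at most one;
#' earlier groups take the remainder). This mirrors assigning the stream
#' acquired along a row driven at constant speed to the consecutive 5-vine
#' sub-replicate units.
#'
#' @param batch a \linkS4class{SpectraBatch} in acquisition order
#' @param nGroups number of contiguous groups (default 3)
#' @return a list of `nGroups` SpectraBatch objects; concatenating them in
#'   order restores the input
#' @export
allocateStream <- function(batch, nGroups = 3L) {
  n <- nSpectra(batch)
  nGroups <- as.integer(nGroups)
  if (n == 0L) stop("cannot allocate an empty stream")
  if (nGroups < 1L) stop("nGroups must be at least 1")
  if (nGroups > n)
    stop(sprintf("nGroups (%d) exceeds the stream size (%d)", nGroups, n))
  sizes <- rep(n %/% nGroups, nGroups)
  r <- n %% nGroups
  if (r) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(nGroups), function(i) {
    out <- batch[, starts[i]:ends[i]]
    out
  })
}

#' Average a batch into one mean spectrum
#'
#' Channel-wise arithmetic mean over all spectra of the batch. Metadata
#' columns that are constant across the group are inherited; `timestamp` and
#' `position_m` become group means; anything else is `NA`.
#'
#' @param batch a non-empty \linkS4class{SpectraBatch}
#' @return a single-spectrum SpectraBatch
#' @export
averageSpectra <- function(batch) {
  if (nSpectra(batch) == 0L) stop("cannot average an empty batch")
  m <- spectraMeta(batch)
  inherit <- lapply(setdiff(.metaColumns, c("timestamp", "position_m")),
    function(col) {
      u <- unique(m[[col]])
      if (length(u) == 1L) u else NA
    })
  names(inherit) <- setdiff(.metaColumns, c("timestamp", "position_m"))
  meta <- as.data.frame(inherit, stringsAsFactors = FALSE)
  meta$timestamp <- if (all(is.na(m$timestamp))) NA else
    mean(m$timestamp, na.rm = TRUE)
  meta$position_m <- if (all(is.na(m$position_m))) NA else
    mean(m$position_m, na.rm = TRUE)
  SpectraBatch(rowMeans(absorbance(batch)), spectraGrid(batch), meta)
}

# concatenate batches sharing one grid (acquisition order = argument order)
.bindBatches <- function(batches) {
  stopifnot(length(batches) >= 1L)
  g <- spectraGrid(batches[[1L]])
  for (b in batches[-1L])
    if (!isTRUE(all.equal(wavelengths(spectraGrid(b)), wavelengths(g))))
      stop("batches are on different wavelength grids")
  SpectraBatch(do.call(cbind, lapply(batches, absorbance)), g,
               do.call(rbind, lapply(batches, spectraMeta)))
}

#' Read / write SpectraBatch CSV
#'
#' Wide UTF-8 CSV interchange: metadata columns
#' `date,side,replicate_id,sub_unit,timestamp,class_tag,position_m` followed
#' by one absorbance column per channel named `a<wavelength>`. Values are
#' written with 17 significant digits so a write/read round trip restores
#' every absorbance bitwise.
#'
#' @param path file path
#' @return `readBatch` returns a \linkS4class{SpectraBatch}; `writeBatch`
#'   returns `path` invisibly
#' @export
readBatch <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty spectra file: ", path)
  isA <- grepl("^a[0-9]+(\\.[0-9]+)?$", colnames(df))
  wl <- as.numeric(sub("^a", "", colnames(df)[isA]))
  if (length(wl) < 2L) stop("no absorbance columns found in ", path)
  steps <- diff(wl)
  if (any(abs(steps - steps[1L]) > 1e-9))
    stop("absorbance columns are not on a regular wavelength grid")
  grid <- makeGrid(wl[1L], wl[length(wl)], steps[1L])
  vals <- t(as.matrix(df[, isA, drop = FALSE]))
  if (nrow(vals) != nChannels(grid))
    stop("channel count does not match the wavelength header")
  if (!all(is.finite(vals)))
    stop("non-finite or missing absorbance values in ", path)
  SpectraBatch(vals, grid, df[, !isA, drop = FALSE])
}

#' @rdname readBatch
#' @param batch a \linkS4class{SpectraBatch}
#' @export
writeBatch <- function(batch, path) {
  m <- spectraMeta(batch)
  a <- t(absorbance(batch))
  num <- matrix(sprintf("%.17g", a), nrow = nrow(a))
  colnames(num) <- sprintf("a%g", wavelengths(spectraGrid(batch)))
  out <- cbind(m[, .metaColumns, drop = FALSE], as.data.frame(num))
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
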