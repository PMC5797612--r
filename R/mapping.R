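# uniform cubic B-spline basis values at parameter s in [0, 1]
.bsplineBasis <- function(s) {
  cbind((1 - s)^3 / 6,
        (3 * s^3 - 6 * s^2 + 4) / 6,
        (-3 * s^3 + 3 * s^2 + 3 * s + 1) / 6,
        s^3 / 6)
}

# BA algorithm: fit one (m x n cell) control lattice to scattered residuals.
# Returns the (m+3) x (n+3) control matrix (unsupported control points 0).
.baFit <- function(u, v, z, m, n) {
  iu <- pmin(floor(u), m - 1); su <- u - iu
  iv <- pmin(floor(v), n - 1); sv <- v - iv
  Bu <- .bsplineBasis(su); Bv <- .bsplineBasis(sv)
  sumw2 <- rowSums(Bu^2) * rowSums(Bv^2)   # sum over the 16 weights squared
  num <- numeric((m + 3) * (n + 3))
  den <- numeric((m + 3) * (n + 3))
  for (k in 1:4) for (l in 1:4) {
    w <- Bu[, k] * Bv[, l]
    idx <- (iu + k - 1) + (iv + l - 1) * (m + 3) + 1
    phi <- w * z / sumw2
    sN <- rowsum(w^2 * phi, idx)
    sD <- rowsum(w^2, idx)
    ii <- as.integer(rownames(sN))
    num[ii] <- num[ii] + sN
    den[ii] <- den[ii] + sD
  }
  ctl <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
  matrix(ctl, m + 3, n + 3)
}

# evaluate one lattice at parameter coordinates (u, v)
.baEval <- function(ctl, u, v) {
  m <- nrow(ctl) - 3; n <- ncol(ctl) - 3
  iu <- pmin(floor(u), m - 1); su <- u - iu
  iv <- pmin(floor(v), n - 1); sv <- v - iv
  Bu <- .bsplineBasis(su); Bv <- .bsplineBasis(sv)
  out <- numeric(length(u))
  for (k in 1:4) for (l in 1:4)
    out <- out + Bu[, k] * Bv[, l] * ctl[cbind(iu + k, iv + l)]
  out
}

#' Multilevel B-spline approximation of scattered points
#'
#' Lee-Wolberg-Shin MBA: a hierarchy of uniform cubic B-spline control
#' lattices, starting from a 4 x 4 control lattice (one cell) and refining
#' dyadically; each level is fitted (BA algorithm) to the residuals of the
#' sum of the coarser levels. The global data mean is used as the level-0
#' surface, so a constant field is reproduced exactly. The summed surface is
#' evaluated at cell centres of a regular raster.
#'
#' @param points data.frame with columns `x`, `y` (metres, local plot frame)
#'   and `value` (e.g. predicted psi_s, MPa)
#' @param cellSize raster cell size (m)
#' @param extent optional `c(xmin, xmax, ymin, ymax)`; defaults to the point
#'   bounding box padded by one cell
#' @param levels number of refinement levels (default 8)
#' @param details if `TRUE`, also return the per-level RMS residuals at the
#'   data points (monotone non-increasing across levels; the pointwise
#'   max-norm can wiggle at coarse lattices) and a `predict(x, y)` evaluator
#' @return a \linkS4class{MapGrid}, or (with `details`) a list with `grid`,
#'   `residuals` and `predict`
#' @export
mbaInterpolate <- function(points, cellSize = 1, extent = NULL, levels = 8L,
                           details = FALSE) {
  points <- as.data.frame(points)
  if (!nrow(points)) stop("empty point set")
  if (levels < 1L) stop("need at least one level")
  if (is.null(extent))
    extent <- c(min(points$x) - cellSize, max(points$x) + cellSize,
                min(points$y) - cellSize, max(points$y) + cellSize)
  inside <- points$x >= extent[1L] & points$x <= extent[2L] &
    points$y >= extent[3L] & points$y <= extent[4L]
  if (!any(inside)) stop("no point lies inside the grid extent")
  points <- points[inside, ]
  dx <- extent[2L] - extent[1L]; dy <- extent[4L] - extent[3L]
  un <- (points$x - extent[1L]) / dx
  vn <- (points$y - extent[3L]) / dy
  offset <- mean(points$value)
  z <- points$value - offset
  lattices <- vector("list", levels)
  residMax <- numeric(levels)
  for (lev in seq_len(levels)) {
    m <- 2^(lev - 1L)
    ctl <- .baFit(un * m, vn * m, z, m, m)
    z <- z - .baEval(ctl, un * m, vn * m)
    lattices[[lev]] <- ctl
    residMax[lev] <- sqrt(mean(z^2))
  }
  evalSurface <- function(px, py) {
    uu <- pmin(pmax((px - extent[1L]) / dx, 0), 1)
    vv <- pmin(pmax((py - extent[3L]) / dy, 0), 1)
    out <- rep(offset, length(px))
    for (lev in seq_len(levels)) {
      m <- 2^(lev - 1L)
      out <- out + .baEval(lattices[[lev]], uu * m, vv * m)
    }
    out
  }
  ncols <- max(1L, ceiling(dx / cellSize))
  nrows <- max(1L, ceiling(dy / cellSize))
  cx <- extent[1L] + (seq_len(ncols) - 0.5) * cellSize
  cy <- extent[3L] + (seq_len(nrows) - 0.5) * cellSize
  vals <- matrix(evalSurface(rep(cx, times = nrows),
                             rep(rev(cy), each = ncols)),
                 nrow = nrows, ncol = ncols, byrow = TRUE)
  grid <- new("MapGrid", xll = extent[1L], yll = extent[3L],
              cellSize = cellSize, values = vals, nodata = -9999)
  if (details)
    list(grid = grid, residuals = residMax, predict = evalSurface)
  else grid
}

setMethod("show", "MapGrid", function(object) {
  cat(sprintf("MapGrid: %d x %d cells of %g m, origin (%g, %g), range %.3f..%.3f\n",
              nrow(object@values), ncol(object@values), object@cellSize,
              object@xll, object@yll,
              min(object@values, na.rm = TRUE),
              max(object@values, na.rm = TRUE)))
})

#' Write / read an ESRI ASCII grid
#'
#' Plain-text `.asc` raster: the six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows north to south.
#' Values are written with 10 significant digits; `NA` cells become the
#' nodata marker.
#'
#' @param grid a \linkS4class{MapGrid}
#' @param path output path (conventionally `.asc`)
#' @return `exportGrid` returns `path` invisibly; `readGrid` a MapGrid
#' @export
exportGrid <- function(grid, path) {
  v <- grid@values
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid@xll),
           sprintf("yllcorner %.10g", grid@yll),
           sprintf("cellsize %.10g", grid@cellSize),
           sprintf("NODATA_value %.10g", grid@nodata))
  v[is.na(v)] <- grid@nodata
  body <- apply(v, 1L, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname exportGrid
#' @export
readGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "[[:space:]]+")
  keys <- tolower(vapply(hdr, `[[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[[`, "", 2L))
  names(vals) <- keys
  v <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1L]])))
  v[v == vals["nodata_value"]] <- NA
  new("MapGrid", xll = unname(vals["xllcorner"]),
      yll = unname(vals["yllcorner"]), cellSize = unname(vals["cellsize"]),
      values = v, nodata = unname(vals["nodata_value"]))
}

#' Map predicted water status for one date
#'
#' Predicts psi_s for every sample of the chosen date with the pipeline's
#' fitted model and interpolates the predictions (placed at sub-unit
#' centroids) into a continuous surface.
#'
#' @param result a [runPipeline()] result
#' @param date which campaign date to map (default: first)
#' @param cellSize raster cell size (m)
#' @param levels MBA refinement levels
#' @return a \linkS4class{MapGrid}
#' @export
psiMap <- function(result, date = NULL, cellSize = 0.5, levels = 6L) {
  ds <- result$dataset
  if (is.null(date)) date <- ds@labels$date[1L]
  sel <- ds@labels$date == date
  if (!any(sel)) stop("no samples for date ", date)
  pts <- data.frame(x = ds@labels$x[sel], y = ds@labels$y[sel],
                    value = predictPsi(result$model, ds[sel]))
  mbaInterpolate(pts, cellSize = cellSize, levels = levels)
}
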