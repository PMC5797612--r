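# Seed plumbing: one campaign seed, deterministic sub-seeds per operation so
# streams for different dates/replicates are independent but reproducible.
.subSeed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(paste(..., sep = "|")))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(max(1, h))
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Vapour pressure deficit from air temperature and relative humidity
#'
#' Tetens saturation vapour pressure over liquid water:
#' `es = 0.6108 * exp(17.27 * T / (T + 237.3))` (kPa), and
#' `VPD = es * (1 - RH/100)`.
#'
#' @param airT air temperature (degrees C); vectorised
#' @param RH relative humidity (percent, in \[0, 100\])
#' @return VPD in kPa (0 at saturation)
#' @examples
#' vpd(32.0, 36.5)  # ~3.02 kPa
#' @export
vpd <- function(airT, RH) {
  if (any(RH < 0 | RH > 100)) stop("RH must be within [0, 100]")
  es <- 0.6108 * exp(17.27 * airT / (airT + 237.3))
  es * (1 - RH / 100)
}

#' Midday weather records of the emulated campaigns
#'
#' Solar-noon air temperature and relative humidity for each measurement
#' date of the 2015 (9 dates) and 2016 (6 dates) seasons, with VPD computed
#' by [vpd()].
#'
#' @param season `"2015"` or `"2016"`
#' @return data.frame with columns `date`, `air_T`, `RH`, `VPD`
#' @export
envConditions <- function(season = c("2015", "2016")) {
  season <- match.arg(season)
  if (season == "2015") {
    d <- data.frame(
      date = c("2015-07-23", "2015-07-28", "2015-08-06", "2015-08-12",
               "2015-08-19", "2015-08-26", "2015-09-07", "2015-09-11",
               "2015-09-18"),
      air_T = c(29.2, 28.2, 31.6, 32.0, 26.9, 31.1, 20.4, 25.4, 20.4),
      RH = c(44.0, 35.0, 37.5, 36.5, 20.0, 33.5, 42.0, 50.0, 39.0))
  } else {
    d <- data.frame(
      date = c("2016-07-07", "2016-07-13", "2016-07-20", "2016-07-28",
               "2016-08-11", "2016-08-23"),
      air_T = c(27.2, 18.7, 29.1, 29.2, 22.6, 32.8),
      RH = c(53.0, 48.5, 40.5, 22.5, 38.0, 32.5))
  }
  d$VPD <- vpd(d$air_T, d$RH)
  d
}

#' Build a synthetic vineyard trial design
#'
#' A completely randomized block design: within each block, the treatment
#' order across adjacent field replicates is randomized (by `seed`). Each
#' replicate is a 25-vine monitored row of which the middle 15 vines are
#' measured, split into three 5-vine sub-replicate units; one randomly
#' tagged vine per sub-unit carries the pressure-chamber reference.
#'
#' @param dates campaign dates (character); `"2015"`/`"2016"` pick the
#'   built-in campaign calendars
#' @param blocks number of blocks (default 4)
#' @param treatments treatment labels (default T0/T1/T2 irrigation regimes)
#' @param vineSpacing,rowSpacing vine and row spacing (m)
#' @param seed randomization seed for treatment order and tagged vines
#' @return a \linkS4class{FieldDesign}
#' @examples
#' d <- buildDesign("2015")
#' referenceSlots(d)  # 324
#' @export
buildDesign <- function(dates = "2015", blocks = 4L,
                        treatments = c("T0", "T1", "T2"),
                        vineSpacing = 1.20, rowSpacing = 2.60, seed = 20150723) {
  if (length(dates) == 1L && dates %in% c("2015", "2016"))
    dates <- envConditions(dates)$date
  blocks <- as.integer(blocks)
  if (blocks < 1L) stop("configuration error: need at least one block")
  if (!length(dates)) stop("configuration error: need at least one date")
  if (!length(treatments)) stop("configuration error: need a treatment")
  nt <- length(treatments)
  layout <- .withSeed(.subSeed(seed, "layout"), {
    rows <- do.call(rbind, lapply(seq_len(blocks), function(b) {
      ord <- sample(nt)
      data.frame(block = b, treatment = treatments[ord],
                 slot = seq_len(nt))
    }))
    rows$replicate_id <- sprintf("B%dR%d", rows$block, rows$slot)
    idx <- seq_len(nrow(rows))
    # replicates stacked across the plot; each spans 3 rows, middle monitored
    rows$x0 <- 0
    rows$y0 <- (3 * (idx - 1) + 1) * rowSpacing
    rows
  })
  tags <- .withSeed(.subSeed(seed, "tags"), {
    do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
      data.frame(replicate_id = layout$replicate_id[i], sub_unit = 1:3,
                 vine_id = 5L * (1:3) + sample(5L, 3L, replace = TRUE))
    }))
  })
  layout <- merge(layout, tags, by = "replicate_id", sort = FALSE)
  new("FieldDesign", blocks = blocks, treatments = as.character(treatments),
      dates = as.character(dates), vinesPerReplicate = 25L,
      subUnitsPerReplicate = 3L, taggedVinesPerReplicate = 3L,
      vineSpacing = vineSpacing, rowSpacing = rowSpacing, layout = layout)
}

#' @rdname buildDesign
#' @param design a \linkS4class{FieldDesign}
#' @return `designTable` returns one row per (date, replicate, sub-unit)
#'   reference slot: date, block, treatment, replicate_id, sub_unit, vine_id
#'   and the plot-frame coordinates of the sub-unit centroid (x, y, metres)
#' @export
designTable <- function(design) {
  lay <- design@layout
  out <- do.call(rbind, lapply(design@dates, function(d) {
    data.frame(date = d, block = lay$block, treatment = lay$treatment,
               replicate_id = lay$replicate_id, sub_unit = lay$sub_unit,
               vine_id = lay$vine_id,
               x = lay$x0 + (5 * lay$sub_unit + 3) * design@vineSpacing,
               y = lay$y0)
  }))
  rownames(out) <- NULL
  out
}

#' @rdname buildDesign
#' @return `referenceSlots` returns the number of reference measurements the
#'   design implies: replicates x tagged vines x dates
#' @export
referenceSlots <- function(design) {
  design@blocks * length(design@treatments) *
    design@taggedVinesPerReplicate * length(design@dates)
}

setMethod("show", "FieldDesign", function(object) {
  cat(sprintf(paste0("FieldDesign: %d blocks x %d treatments ",
                     "(%s), %d dates, %d reference slots\n"),
              object@blocks, length(object@treatments),
              paste(object@treatments, collapse = "/"),
              length(object@dates), referenceSlots(object)))
})

# Seasonal shape vectors (population mean 0, SD 1): irrigated vines dry down
# to mid August, recover after the early-September rains, then dip again;
# non-irrigated vines decline steadily with a late slight recovery.
.standardize <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
.shapes <- list(
  "2015" = list(
    T0 = .standardize(c(0.8, 0.5, 0.0, -0.6, -0.6, -0.5, 0.4, 0.6, -0.6)),
    T1 = .standardize(c(0.9, 0.6, 0.0, -0.7, -0.6, -0.4, 0.4, 0.5, -0.7)),
    T2 = .standardize(c(1.4, 1.1, 0.6, 0.1, -0.4, -0.8, -1.2, -0.9, -0.7))),
  "2016" = list(
    T0 = .standardize(c(1.0, 0.5, 0.1, -0.5, -0.5, -0.6)),
    T1 = .standardize(c(1.2, 0.8, 0.3, -0.2, -0.8, -1.3)),
    T2 = .standardize(c(1.2, 0.9, 0.3, -0.2, -0.8, -1.4))))

# Pooled descriptive statistics of psi_s per treatment (MPa)
.psiStats <- list(
  "2015" = data.frame(
    treatment = c("T0", "T1", "T2"),
    min = c(-1.35, -1.65, -2.25), max = c(-0.55, -0.65, -1.10),
    mean = c(-0.85, -1.16, -1.67), sd = c(0.161, 0.235, 0.284)),
  "2016" = data.frame(
    treatment = c("T0", "T1", "T2"),
    min = c(-1.45, -1.70, -1.95), max = c(-0.75, -1.00, -0.85),
    mean = c(-1.08, -1.30, -1.36), sd = c(0.151, 0.160, 0.254)))

#' Default stem water potential trajectories
#'
#' Per-treatment, per-date mean/SD/bounds of midday stem water potential.
#' The pooled mean and SD over dates match the campaign's descriptive
#' statistics: a fraction `f` of the total SD is placed in the seasonal
#' movement of the date means and the rest (`sqrt(1 - f^2)`) in the
#' within-date SD, so pooling over dates recovers the total.
#'
#' @param season `"2015"` or `"2016"`
#' @param dateShareSD fraction `f` of the pooled SD carried by the seasonal
#'   trajectory of date means (default 0.6)
#' @return data.frame with columns `treatment`, `date`, `mean`, `sd`,
#'   `min`, `max` (all MPa)
#' @export
defaultTrajectories <- function(season = c("2015", "2016"),
                                dateShareSD = 0.6) {
  season <- match.arg(season)
  stats <- .psiStats[[season]]
  dates <- envConditions(season)$date
  out <- do.call(rbind, lapply(seq_len(nrow(stats)), function(i) {
    tr <- stats$treatment[i]
    shape <- .shapes[[season]][[tr]]
    data.frame(treatment = tr, date = dates,
               mean = stats$mean[i] + dateShareSD * stats$sd[i] * shape,
               sd = sqrt(1 - dateShareSD^2) * stats$sd[i],
               min = stats$min[i], max = stats$max[i])
  }))
  rownames(out) <- NULL
  out
}

#' Simulate reference stem water potential measurements
#'
#' Draws one psi_s per tagged vine per date as the trajectory's date mean
#' plus Gaussian noise (trajectory SD), hard-clipped to the trajectory
#' bounds. Reproducible for a fixed seed.
#'
#' @param design a \linkS4class{FieldDesign}
#' @param trajectories data.frame as returned by [defaultTrajectories()];
#'   every (treatment, date) pair of the design must be present
#' @param seed integer seed
#' @return data.frame: date, block, treatment, replicate_id, sub_unit,
#'   vine_id, psi_MPa, x, y (sub-unit centroid coordinates, m)
#' @export
simulatePsi <- function(design, trajectories, seed = 1L) {
  slots <- designTable(design)
  key <- paste(slots$treatment, slots$date)
  tkey <- paste(trajectories$treatment, trajectories$date)
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    stop("configuration error: no trajectory for ",
         paste(miss, collapse = "; "))
  }
  tr <- trajectories[idx, ]
  slots$psi_MPa <- .withSeed(.subSeed(seed, "psi"), {
    pmin(pmax(rnorm(nrow(slots), tr$mean, tr$sd), tr$min), tr$max)
  })
  slots
}

#' On-the-go stream generator configuration
#'
#' Defaults emulate the acquisition geometry (24 Hz at 5 km/h along
#' 1.20 m-spaced vines) and a leaf absorbance model in which the depth of
#' the water (OH) bands near 1450 and 1940 nm depends affinely on the
#' vine's stem water potential: `depth = alpha0 + alpha1 * psi` with
#' `alpha1 > 0`, so wetter (less negative) vines absorb more.
#'
#' @param acquisitionRate spectra per second (Hz)
#' @param vehicleSpeed km/h
#' @param contaminationFraction fraction of emitted spectra drawn from the
#'   wood / metal / gap contaminant archetypes (equal shares)
#' @param bandCenters,bandWidths centres and Gaussian widths (nm) of the two
#'   OH bands
#' @param alpha0,alpha1 affine coefficients of the band-depth model
#'   (absorbance units; per MPa for `alpha1`)
#' @param baselineRange additive baseline offset, drawn uniformly per
#'   spectrum (absorbance units)
#' @param scatterRange multiplicative scatter factor, uniform per spectrum
#' @param noiseSD i.i.d. per-channel noise SD (absorbance units)
#' @param depthJitterSD per-spectrum (leaf-to-leaf) SD of band depth
#' @param vineSD SD of untagged-vine psi deviations from the sub-unit
#'   reference (MPa)
#' @param tagSD SD of the sub-unit-level mismatch between the canopy sensed
#'   on-the-go and the bagged reference leaf of the tagged vine (MPa); this
#'   offset is shared by the whole 5-vine sub-unit, so it does not average
#'   out and sets the irreducible prediction error floor
#' @param dateDepthSD SD of a per-date offset of band depth (absorbance
#'   units) shared by every spectrum of the date - a day-level environmental
#'   confounder
#' @param dateSpectralSD amplitude SD of smooth per-date spectral clutter
#'   (absorbance units), also a day-level confounder
#' @return a validated configuration list of class `streamConfig`
#' @export
streamConfig <- function(acquisitionRate = 24, vehicleSpeed = 5,
                         contaminationFraction = 0.15,
                         bandCenters = c(1450, 1940),
                         bandWidths = c(40, 60),
                         alpha0 = 1.0, alpha1 = 0.25,
                         baselineRange = c(0.05, 0.35),
                         scatterRange = c(0.7, 1.3),
                         noiseSD = 0.02, depthJitterSD = 0.03,
                         vineSD = 0.10, tagSD = 0.15,
                         dateDepthSD = 0.03, dateSpectralSD = 0.02) {
  cfg <- list(acquisitionRate = acquisitionRate, vehicleSpeed = vehicleSpeed,
              contaminationFraction = contaminationFraction,
              bandCenters = bandCenters, bandWidths = bandWidths,
              alpha0 = alpha0, alpha1 = alpha1,
              baselineRange = baselineRange, scatterRange = scatterRange,
              noiseSD = noiseSD, depthJitterSD = depthJitterSD,
              vineSD = vineSD, tagSD = tagSD, dateDepthSD = dateDepthSD,
              dateSpectralSD = dateSpectralSD)
  if (!(cfg$acquisitionRate > 0)) stop("acquisition rate must be positive")
  if (!(cfg$vehicleSpeed > 0)) stop("vehicle speed must be positive")
  if (cfg$contaminationFraction < 0 || cfg$contaminationFraction >= 1)
    stop("contamination fraction must be in [0, 1)")
  if (cfg$noiseSD < 0) stop("noise SD must be non-negative")
  class(cfg) <- "streamConfig"
  cfg
}

# fixed leaf matrix background: two broad minor bands over a flat base
.leafMatrix <- function(wl) {
  0.45 + 0.25 * exp(-0.5 * ((wl - 1200) / 80)^2) +
    0.18 * exp(-0.5 * ((wl - 1700) / 120)^2)
}

.waterBands <- function(wl, centers, widths) {
  exp(-0.5 * ((wl - centers[1L]) / widths[1L])^2) +
    0.85 * exp(-0.5 * ((wl - centers[2L]) / widths[2L])^2)
}

# smooth per-date clutter: three random Gaussian bumps
.dateClutter <- function(wl, sdAmp) {
  a <- rnorm(3L, 0, sdAmp)
  ctr <- runif(3L, 1150, 2050)
  wid <- runif(3L, 60, 150)
  colSums(a * exp(-0.5 * ((matrix(wl, 3L, length(wl), byrow = TRUE) - ctr) /
                            wid)^2))
}

#' Simulate one on-the-go spectral stream
#'
#' Emits the raw spectral stream of one pass along one replicate's monitored
#' row (all 25 vines) for one date and canopy side, in acquisition order.
#' The emitted count is `round(rate * rowLength / speed)`. Leaf spectra
#' follow `baseline + scatter * (matrix + depth(psi) * bands + clutter) +
#' noise`; a `contaminationFraction` of spectra are wood, metal or gap
#' archetypes. Each spectrum carries its truth class and sub-unit tags for
#' downstream test oracles.
#'
#' @param design a \linkS4class{FieldDesign}
#' @param psi reference table from [simulatePsi()] (needs the requested
#'   date/replicate rows)
#' @param date,replicateId which pass to emulate
#' @param cfg a [streamConfig()]
#' @param side `"east"` or `"west"`
#' @param seed campaign seed; the pass uses a deterministic sub-seed
#' @param grid wavelength grid (default 1100-2100 nm, 4 nm)
#' @return a \linkS4class{SpectraBatch}
#' @export
simulateStream <- function(design, psi, date, replicateId,
                           cfg = streamConfig(), side = "east", seed = 1L,
                           grid = makeGrid()) {
  ref <- psi[psi$date == date & psi$replicate_id == replicateId, ]
  if (nrow(ref) == 0L)
    stop("no reference psi for date ", date, " replicate ", replicateId)
  wl <- wavelengths(grid)
  L <- design@vinesPerReplicate * design@vineSpacing
  v <- cfg$vehicleSpeed / 3.6
  n <- round(cfg$acquisitionRate * L / v)
  pos <- (seq_len(n) - 0.5) * L / n
  vine <- pmin(floor(pos / design@vineSpacing) + 1L, design@vinesPerReplicate)
  subUnit <- integer(n)
  measured <- vine >= 6L & vine <= 20L
  subUnit[measured] <- (vine[measured] - 6L) %/% 5L + 1L

  trtMean <- mean(ref$psi_MPa)  # fallback psi level for edge vines
  dateSeed <- .subSeed(seed, "date-effects", date)
  clutter <- .withSeed(dateSeed, .dateClutter(wl, cfg$dateSpectralSD))
  dateDepth <- .withSeed(.subSeed(seed, "date-depth", date),
                         rnorm(1L, 0, cfg$dateDepthSD))

  .withSeed(.subSeed(seed, "stream", date, replicateId, side), {
    # per-vine psi as sensed in the canopy; the bagged reference leaf is
    # offset from its whole sub-unit canopy by a shared N(0, tagSD) term
    suOffset <- rnorm(design@subUnitsPerReplicate, 0, cfg$tagSD)
    vinePsi <- numeric(design@vinesPerReplicate)
    for (k in seq_len(design@vinesPerReplicate)) {
      su <- if (k >= 6L && k <= 20L) (k - 6L) %/% 5L + 1L else 0L
      if (su > 0L) {
        base <- ref$psi_MPa[ref$sub_unit == su] + suOffset[su]
        vinePsi[k] <- if (k %in% ref$vine_id[ref$sub_unit == su]) base
        else base + rnorm(1L, 0, cfg$vineSD)
      } else {
        vinePsi[k] <- trtMean + rnorm(1L, 0, cfg$vineSD)
      }
    }
    cls <- rep("leaf", n)
    if (cfg$contaminationFraction > 0) {
      contam <- runif(n) < cfg$contaminationFraction
      cls[contam] <- sample(c("wood", "metal", "gap"), sum(contam),
                            replace = TRUE)
    }
    baseline <- runif(n, cfg$baselineRange[1L], cfg$baselineRange[2L])
    scatter <- runif(n, cfg$scatterRange[1L], cfg$scatterRange[2L])
    depth <- cfg$alpha0 + cfg$alpha1 * vinePsi[vine] + dateDepth +
      rnorm(n, 0, cfg$depthJitterSD)
    M <- .leafMatrix(wl)
    B <- .waterBands(wl, cfg$bandCenters, cfg$bandWidths)
    A <- matrix(0, nChannels(grid), n)
    for (i in seq_len(n)) {
      A[, i] <- switch(cls[i],
        leaf = baseline[i] + scatter[i] * (M + depth[i] * B + clutter),
        wood = baseline[i] + scatter[i] *
          (0.30 + 0.45 * exp(-0.5 * ((wl - 1200) / 100)^2)),
        metal = rep(0.12, length(wl)),
        gap = rep(0.02, length(wl)))
    }
    A <- A + matrix(rnorm(length(A), 0,
                          ifelse(rep(cls == "gap", each = length(wl)),
                                 3 * cfg$noiseSD, cfg$noiseSD)),
                    nrow(A), n)
    meta <- data.frame(date = date, side = side, replicate_id = replicateId,
                       sub_unit = subUnit,
                       timestamp = (seq_len(n) - 0.5) / cfg$acquisitionRate,
                       class_tag = cls, position_m = pos)
    SpectraBatch(A, grid, meta)
  })
}

#' Simulate a complete campaign
#'
#' Convenience wrapper: builds the design, draws the reference psi_s table
#' and generates every (date, replicate) stream for the requested side(s).
#' For the full default campaigns this holds on the order of 5e4 spectra;
#' [runPipeline()] generates streams one at a time instead.
#'
#' @param season `"2015"` or `"2016"` (or a character vector of dates)
#' @param side one or both of `"east"`, `"west"`
#' @param seed campaign seed
#' @param cfg a [streamConfig()]
#' @param blocks number of blocks (default 4)
#' @param trajectories psi trajectories; default [defaultTrajectories()]
#' @return list with `design`, `trajectories`, `psi` (reference table),
#'   `env` (weather, for the built-in seasons) and `streams`, a list keyed
#'   `date|replicate|side`
#' @export
simulateCampaign <- function(season = "2015", side = "east", seed = 1L,
                             cfg = streamConfig(), blocks = 4L,
                             trajectories = NULL) {
  design <- buildDesign(season, blocks = blocks)
  if (is.null(trajectories)) {
    stopifnot(length(season) == 1L, season %in% c("2015", "2016"))
    trajectories <- defaultTrajectories(season)
  }
  psi <- simulatePsi(design, trajectories, seed)
  streams <- list()
  for (d in design@dates)
    for (r in design@layout$replicate_id)
      for (s in side)
        streams[[paste(d, r, s, sep = "|")]] <-
          simulateStream(design, psi, d, r, cfg, s, seed)
  env <- if (length(season) == 1L && season %in% c("2015", "2016"))
    envConditions(season) else NULL
  list(design = design, trajectories = trajectories, psi = psi,
       env = env, streams = streams)
}
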