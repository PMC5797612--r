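# small synthetic campaign configuration for fast end-to-end tests
smallConfig <- function(seed = 1L, nDates = 3L, blocks = 2L, side = "east",
                        stream = list(), ...) {
  tr <- defaultTrajectories("2015")
  dates <- unique(tr$date)[seq_len(nDates)]
  defaultConfig(seed = seed,
                simulate = list(season = dates, side = side, blocks = blocks,
                                trajectories = tr[tr$date %in% dates, ],
                                stream = stream),
                ...)
}

# deterministic noise-free stream configuration (args override the zeros)
quietStream <- function(...) {
  quiet <- list(contaminationFraction = 0, noiseSD = 0, depthJitterSD = 0,
                vineSD = 0, tagSD = 0, dateDepthSD = 0, dateSpectralSD = 0,
                baselineRange = c(0, 0), scatterRange = c(1, 1))
  do.call(streamConfig, utils::modifyList(quiet, list(...)))
}

# scattered points with guaranteed separation (jittered grid), so the finest
# B-spline lattice can resolve every point individually
separatedPoints <- function(n = 50, seed = 1) {
  set.seed(seed)
  g <- expand.grid(x = seq(1.25, 28.75, 2.5), y = seq(1.7, 18.7, 3.4))
  pts <- g[sample(nrow(g), n), ]
  pts$x <- pts$x + runif(n, -0.7, 0.7)
  pts$y <- pts$y + runif(n, -1.0, 1.0)
  pts$value <- -runif(n, 0.6, 2.2)
  rownames(pts) <- NULL
  pts
}

# toy batch with prescribed absorbance columns
toyBatch <- function(values, grid = makeGrid(0, (nrow(values) - 1) * 2, 2),
                     meta = NULL) {
  SpectraBatch(values, grid, meta)
}

# independent F quantile through the beta-quantile identity
qfBeta <- function(p, d1, d2) {
  b <- qbeta(p, d1 / 2, d2 / 2)
  d2 * b / (d1 * (1 - b))
}
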