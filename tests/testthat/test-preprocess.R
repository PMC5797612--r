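test_that("SNV centres and scales each spectrum with the sample SD", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  X <- matrix(rnorm(5 * 40, mean = 2), 5)
  S <- snv(X)
  expect_equal(rowMeans(S), rep(0, 5))
  expect_equal(apply(S, 1, sd), rep(1, 5))
  # affine invariance and idempotence
  expect_equal(snv(3.7 * X[1, ] + 11), S[1, ])
  expect_equal(snv(S), S, tolerance = 1e-12)
  expect_error(snv(rep(1, 10)), "degenerate|constant")
})

test_that("Savitzky-Golay derivatives are exact on polynomials", {
  g <- makeGrid(1100, 2100, 4)
  wl <- wavelengths(g)
  # constant -> zero derivative
  expect_equal(savgol(rep(5, 251), 7, 2, 1, step = 4), rep(0, 245))
  # y = lambda, D1W7 -> slope 1 per nm at every interior channel
  expect_equal(savgol(wl, 7, 2, 1, step = 4), rep(1, 245), tolerance = 1e-9)
  # y = lambda^2, D1W15 -> derivative 2*lambda at interior channels
  got <- savgol(wl^2, 15, 2, 1, step = 4)
  expect_equal(got, 2 * wl[8:244], tolerance = 1e-9)
  # smoothing (deriv 0) reproduces polynomials up to the fitted order
  expect_equal(savgol(3 * wl^2 - wl + 2, 11, 2, 0, step = 4),
               (3 * wl^2 - wl + 2)[6:246], tolerance = 1e-7)
  expect_error(savgol(wl, 8, 2, 1), "odd")
  expect_error(savgol(wl, 7, 2, 3), "polyorder")
  expect_error(savgol(wl, 1, 2, 0), "polynomial order")
})

test_that("Savitzky-Golay matches the signal package filter", {
  skip_if_not_installed("signal")
  x <- sin(seq(0, 6, length.out = 100))
  ours <- savgol(x, 11, 2, 1, step = 1)
  ref <- signal::sgolayfilt(x, p = 2, n = 11, m = 1)
  expect_equal(ours, ref[6:95], tolerance = 1e-12)
  sm <- savgol(x, 9, 3, 0, step = 1)
  ref0 <- signal::sgolayfilt(x, p = 3, n = 9, m = 0)
  expect_equal(sm, ref0[5:96], tolerance = 1e-12)
})

test_that("derivative filtering is linear", {
  x <- rnorm(80); y <- rnorm(80)
  expect_equal(savgol(2 * x + 5 * y, 7, 2, 1),
               2 * savgol(x, 7, 2, 1) + 5 * savgol(y, 7, 2, 1))
})

test_that("preprocessing shorthand parses, prints and composes", {
  steps <- parsePreprocess("SNV+D1W15")
  expect_length(steps, 2)
  expect_equal(steps[[1]]$type, "snv")
  expect_equal(steps[[2]][c("window", "deriv")], list(window = 15L, deriv = 1L))
  expect_equal(preprocessCode(steps), "SNV+D1W15")
  expect_equal(preprocessCode(parsePreprocess("D1W7")), "D1W7")
  expect_error(parsePreprocess("MSC"), "unknown")
  # identity, composition, constant input
  x <- rnorm(251)
  expect_equal(applyPreprocess(x, ""), x)
  expect_equal(applyPreprocess(x, "SNV+D1W15", step = 4),
               savgol(snv(x), 15, 2, 1, step = 4))
  expect_equal(applyPreprocess(rep(3.2, 100), "D1W7"), rep(0, 94))
  # SpectraBatch route trims the grid consistently
  g <- makeGrid(1100, 2100, 4)
  b <- SpectraBatch(matrix(rnorm(251 * 4), 251), g)
  out <- applyPreprocess(b, "SNV+D1W15")
  expect_equal(nChannels(spectraGrid(out)), 237L)
  expect_equal(wavelengths(spectraGrid(out))[1], 1128)
})

test_that("signature filter partitions the batch and rejects flat spectra", {
  cfg <- streamConfig()
  sig <- leafSignature(cfg)
  g <- spectraGrid(sig)
  # the signature itself is retained (self correlation 1)
  self <- signatureFilter(sig, sig)
  expect_true(self$mask)
  # a flat metal archetype has ~zero correlation with the banded signature
  metal <- SpectraBatch(rep(0.12, 251), g)
  expect_false(signatureFilter(metal, sig)$mask)
  r <- cor(rep(1, 251) + rnorm(251, 0, 1e-8), as.numeric(absorbance(sig)))
  expect_lt(abs(r), 0.5)
  # partition is exhaustive and disjoint
  mix <- SpectraBatch(cbind(absorbance(sig), 0.12, absorbance(sig) * 1.3),
                      g)
  fl <- signatureFilter(mix, sig)
  expect_equal(nSpectra(fl$retained) + nSpectra(fl$rejected), 3L)
  expect_equal(fl$mask, c(TRUE, FALSE, TRUE))
  expect_error(signatureFilter(mix, sig, threshold = 1.5), "correlation")
  expect_error(signatureFilter(mix, leafSignature(cfg, grid = makeGrid(1100, 2100, 8))),
               "grid")
})

test_that("filter recall and precision on generator truth tags reach 0.95", {
  d <- buildDesign(dates = "d", blocks = 1L, treatments = "T0")
  tr <- data.frame(treatment = "T0", date = "d", mean = -1.1, sd = 0.1,
                   min = -2, max = -0.6)
  psi <- simulatePsi(d, tr, seed = 2)
  cfg <- streamConfig()
  masks <- lapply(1:4, function(s) {
    st <- simulateStream(d, psi, "d", psi$replicate_id[1], cfg, seed = s)
    list(pred = signatureFilter(st, leafSignature(cfg))$mask,
         truth = spectraMeta(st)$class_tag == "leaf")
  })
  pred <- unlist(lapply(masks, `[[`, "pred"))
  truth <- unlist(lapply(masks, `[[`, "truth"))
  recall <- sum(pred & truth) / sum(truth)
  precision <- sum(pred & truth) / sum(pred)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  # contamination-free stream: retention of at least 99%
  clean <- simulateStream(d, psi, "d", psi$replicate_id[1],
                          streamConfig(contaminationFraction = 0), seed = 9)
  expect_gte(mean(signatureFilter(clean, leafSignature(cfg))$mask), 0.99)
})
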