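test_that("design reference counts follow blocks x treatments x vines x dates", {
  expect_equal(referenceSlots(buildDesign("2015")), 324L)
  expect_equal(referenceSlots(buildDesign("2016")), 216L)
  d1 <- buildDesign(dates = "d1", blocks = 1L, treatments = "T0")
  expect_equal(referenceSlots(d1), 3L)
  # arbitrary configuration
  d <- buildDesign(dates = c("a", "b"), blocks = 5L, treatments = c("x", "y"))
  expect_equal(referenceSlots(d), 5L * 2L * 3L * 2L)
  expect_equal(nrow(designTable(d)), referenceSlots(d))
  expect_error(buildDesign(dates = character(0)), "configuration")
  expect_error(buildDesign("2015", blocks = 0L), "configuration")
})

test_that("each sub-unit holds exactly one tagged vine, disjointly", {
  d <- buildDesign("2015")
  tab <- designTable(d)
  one <- subset(tab, date == d@dates[1])
  expect_equal(nrow(one), 36L)  # 12 replicates x 3 sub-units
  for (r in unique(one$replicate_id)) {
    rows <- one[one$replicate_id == r, ]
    expect_equal(sort(rows$sub_unit), 1:3)
    # tagged vine k of sub-unit u lies among its five vines 5u+1..5u+5
    expect_true(all(rows$vine_id > 5 * rows$sub_unit &
                      rows$vine_id <= 5 * rows$sub_unit + 5))
  }
})

test_that("vpd follows Tetens and reproduces the campaign weather table", {
  expect_equal(vpd(32.0, 36.5), 3.02, tolerance = 0.05 / 3.02)
  expect_equal(vpd(29.1, 40.5), 2.38, tolerance = 0.05 / 2.38)
  expect_equal(vpd(25, 100), 0)
  expect_equal(vpd(0, 0), 0.6108)
  expect_error(vpd(25, 101), "RH")
  expect_error(vpd(25, -1), "RH")
  env <- envConditions("2015")
  expect_equal(nrow(env), 9L)
  expect_true(all(env$VPD >= 0))
})

test_that("simulated psi matches the pooled treatment statistics", {
  tr <- defaultTrajectories("2015")
  d <- buildDesign(dates = "2015", blocks = 40L, treatments = "T0")
  draws <- unlist(lapply(1:3, function(s)
    simulatePsi(d, tr, seed = s)$psi_MPa))
  n <- length(draws)
  expect_gt(n, 3000)
  se <- 0.161 / sqrt(n)
  expect_lt(abs(mean(draws) - (-0.85)), 3 * se)
  expect_lt(abs(sd(draws) - 0.161) / 0.161, 0.10)
  expect_true(all(draws >= -1.35 & draws <= -0.55))
})

test_that("degenerate psi noise and hard clipping behave as stated", {
  d <- buildDesign(dates = c("a", "b"), blocks = 1L, treatments = "T0")
  tr <- data.frame(treatment = "T0", date = c("a", "b"),
                   mean = c(-1, -1.5), sd = 0, min = -2.25, max = -0.55)
  psi <- simulatePsi(d, tr, seed = 7)
  expect_equal(psi$psi_MPa, ifelse(psi$date == "a", -1, -1.5))
  tr$sd <- 50
  psi <- simulatePsi(d, tr, seed = 7)
  expect_true(all(psi$psi_MPa >= -2.25 & psi$psi_MPa <= -0.55))
  expect_error(simulatePsi(d, tr[tr$date == "a", ], seed = 1),
               "configuration")
})

test_that("simulatePsi and simulateStream are seed-reproducible", {
  d <- buildDesign(dates = "d", blocks = 1L, treatments = "T0")
  tr <- data.frame(treatment = "T0", date = "d", mean = -1, sd = 0.2,
                   min = -2, max = -0.6)
  p1 <- simulatePsi(d, tr, seed = 11)
  p2 <- simulatePsi(d, tr, seed = 11)
  expect_identical(p1, p2)
  s1 <- simulateStream(d, p1, "d", p1$replicate_id[1], streamConfig(),
                       seed = 11)
  s2 <- simulateStream(d, p1, "d", p1$replicate_id[1], streamConfig(),
                       seed = 11)
  expect_identical(absorbance(s1), absorbance(s2))
  s3 <- simulateStream(d, p1, "d", p1$replicate_id[1], streamConfig(),
                       seed = 12)
  expect_false(identical(absorbance(s1), absorbance(s3)))
})

test_that("stream geometry emits round(rate x length / speed) spectra", {
  d <- buildDesign(dates = "d", blocks = 1L, treatments = "T0")
  tr <- data.frame(treatment = "T0", date = "d", mean = -1, sd = 0,
                   min = -2, max = -0.6)
  psi <- simulatePsi(d, tr, seed = 1)
  st <- simulateStream(d, psi, "d", psi$replicate_id[1], streamConfig(),
                       seed = 1)
  L <- 25 * 1.20
  expect_equal(nSpectra(st), round(24 * L / (5 / 3.6)))  # 518
  # 24 Hz at 5 km/h is 17.28 spectra per metre of row
  expect_equal(nSpectra(st) / L, 24 / (5 / 3.6), tolerance = 1e-3)
  m <- spectraMeta(st)
  expect_true(all(diff(m$timestamp) > 0))
  expect_equal(sort(unique(m$sub_unit)), 0:3)
  expect_error(simulateStream(d, psi[0, ], "d", "nope", streamConfig()),
               "no reference")
})

test_that("contamination tagging and the affine band-depth model", {
  d <- buildDesign(dates = "d", blocks = 1L, treatments = "T0")
  tr <- data.frame(treatment = "T0", date = "d", mean = -1, sd = 0,
                   min = -2, max = -0.6)
  psi <- simulatePsi(d, tr, seed = 1)
  clean <- simulateStream(d, psi, "d", psi$replicate_id[1], quietStream(),
                          seed = 1)
  expect_true(all(spectraMeta(clean)$class_tag == "leaf"))
  dirty <- simulateStream(d, psi, "d", psi$replicate_id[1],
                          streamConfig(contaminationFraction = 0.3), seed = 1)
  frac <- mean(spectraMeta(dirty)$class_tag != "leaf")
  expect_gt(frac, 0.2); expect_lt(frac, 0.4)
  # equal psi steps give identical absorbance differences (affine depth)
  cfg <- quietStream(alpha1 = 0.25)
  at <- function(level) {
    p <- psi; p$psi_MPa <- level
    absorbance(simulateStream(d, p, "d", psi$replicate_id[1], cfg,
                              seed = 5))[, 200]
  }
  dif1 <- at(-0.8) - at(-1.3)
  dif2 <- at(-1.3) - at(-1.8)
  expect_equal(dif1, dif2, tolerance = 1e-12)
  # a 1 MPa step changes the 1450 nm band depth by |alpha1| at the peak
  difFull <- at(-0.8) - at(-1.8)
  expect_equal(max(difFull), 0.25, tolerance = 0.01)
  wl <- wavelengths(spectraGrid(simulateStream(d, psi, "d",
                                               psi$replicate_id[1], cfg,
                                               seed = 5)))
  expect_lt(abs(wl[which.max(difFull)] - 1450), 8)
  d1940 <- unname(difFull[which.min(abs(wl - 1940))])
  expect_equal(d1940 / max(difFull), 0.85, tolerance = 0.01)
})

test_that("band-depth variance grows with |alpha1| for a fixed psi spread", {
  d <- buildDesign(dates = "d", blocks = 2L, treatments = c("T0", "T2"))
  tr <- data.frame(treatment = c("T0", "T2"), date = "d",
                   mean = c(-0.85, -1.67), sd = c(0.13, 0.23),
                   min = -2.25, max = -0.55)
  psi <- simulatePsi(d, tr, seed = 3)
  depthVar <- function(a1) {
    cfg <- quietStream(alpha1 = a1, vineSD = 0.1)
    at1450 <- unlist(lapply(unique(psi$replicate_id), function(r) {
      st <- simulateStream(d, psi, "d", r, cfg, seed = 3)
      absorbance(st)[88, spectraMeta(st)$class_tag == "leaf"]
    }))
    var(at1450)
  }
  v <- vapply(c(0.1, 0.25, 0.5), depthVar, 0)
  expect_true(all(diff(v) > 0))
})
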