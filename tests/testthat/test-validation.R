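# small labelled dataset with controllable structure
labelledDataset <- function(n = 90, dates = 3, treatments = 3,
                            side = "east", seed = 1) {
  set.seed(seed)
  lb <- expand.grid(sub = seq_len(n / dates / treatments),
                    treatment = paste0("T", seq_len(treatments) - 1),
                    date = paste0("d", seq_len(dates)))
  X <- matrix(rnorm(n * 12), n)
  calibrationDataset(X, -runif(n, 0.6, 2.2),
                     data.frame(date = lb$date, side = side,
                                treatment = lb$treatment,
                                replicate_id = paste0("r", lb$sub),
                                sub_unit = 1L),
                     makeGrid(1, 12, 1))
}

test_that("stratified 80/20 split honours fractions and the seed", {
  ds <- labelledDataset(n = 90)
  sp <- splitCalibration(ds, 0.8, seed = 3)
  expect_equal(length(sp$calibration) + length(sp$external), 90L)
  expect_equal(length(sp$external), 18L)  # 9 strata of 10 -> 2 each
  # no overlap: labels partition the dataset
  key <- function(d) paste(d@labels$date, d@labels$replicate_id,
                           d@labels$treatment, d@labels$sub_unit, d@y)
  expect_length(intersect(key(sp$calibration), key(sp$external)), 0)
  sp2 <- splitCalibration(ds, 0.8, seed = 3)
  expect_identical(sp2$external@y, sp$external@y)
  sp3 <- splitCalibration(ds, 0.8, seed = 4)
  expect_false(identical(sp3$external@y, sp$external@y))
  # single stratum, even split
  one <- labelledDataset(n = 10, dates = 1, treatments = 1)
  sp5 <- splitCalibration(one, 0.5, seed = 1)
  expect_equal(length(sp5$calibration), 5L)
  expect_error(splitCalibration(ds, 1.2), "fraction")
  tiny <- labelledDataset(n = 3, dates = 3, treatments = 1)
  w <- capture_warnings(splitCalibration(tiny, 0.8))
  expect_true(any(grepl("fewer than 2", w)))
})

test_that("venetian folds interleave positions i, i+n, i+2n, ...", {
  f <- venetianFolds(10, 5)
  expect_equal(which(f == 1), c(1L, 6L))
  expect_equal(which(f == 2), c(2L, 7L))
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(tabulate(venetianFolds(324, 10)), c(rep(33, 4), rep(32, 6)))
  # n folds = leave-one-out; one fold errors
  expect_equal(venetianFolds(7, 7), 1:7)
  expect_error(venetianFolds(10, 1), "two folds")
  expect_error(venetianFolds(5, 6), "more folds")
})

test_that("leave-one-day-out builds one fold per date", {
  dates <- rep(paste0("d", 1:9), each = 4)
  f <- lodoFolds(dates)
  expect_equal(length(unique(f)), 9L)
  expect_true(all(tapply(dates, f, function(d) length(unique(d))) == 1))
  # union of folds = dataset, pairwise disjoint (a partition by construction)
  expect_length(f, length(dates))
  expect_error(lodoFolds(rep("d1", 5)), "two dates")
  ds <- labelledDataset(n = 30, dates = 2)
  expect_equal(sort(unique(lodoFolds(ds))), 1:2)
})

test_that("cross-validation pools every calibration sample exactly once", {
  ds <- labelledDataset(n = 90)
  folds <- venetianFolds(90, 10)
  cv <- crossValidate(ds, folds, maxLV = 5)
  expect_equal(nrow(cv), 5L)
  expect_true(all(cv$cvRMSE > 0))
  # noiseless linear data: CV error collapses at the true rank
  set.seed(9)
  scores <- matrix(rnorm(90 * 2), 90)
  Xlin <- scores %*% matrix(rnorm(2 * 12), 2)
  lin <- calibrationDataset(Xlin, -(2 + scores %*% c(0.1, 0.1)),
                            ds@labels, ds@grid)
  cvl <- crossValidate(lin, folds, maxLV = 3)
  expect_lt(cvl$cvRMSE[2], 1e-10)
  expect_error(crossValidate(ds, folds[-1], 5), "match")
})

test_that("date-confounded data make LODO harder than venetian blinds", {
  worse <- vapply(1:10, function(s) {
    cfg <- smallConfig(seed = s, nDates = 4, blocks = 2)
    res <- runPipeline(cfg)
    res$report$CV_RMSE_lodo >= res$report$CV_RMSE_venetian
  }, TRUE)
  expect_gte(sum(worse), 8)
})

test_that("balanced east & west merging equalises cells and sizes", {
  east <- labelledDataset(n = 90, side = "east", seed = 1)
  west <- labelledDataset(n = 90, side = "west", seed = 2)
  merged <- balancedMerge(east, west, seed = 5)
  expect_equal(length(merged), 90L)
  expect_equal(sum(merged@labels$side == "east"), 45L)
  counts <- table(merged@labels$side,
                  paste(merged@labels$treatment, merged@labels$date))
  expect_true(all(abs(counts["east", ] - counts["west", ]) <= 1))
  m2 <- balancedMerge(east, west, seed = 5)
  expect_identical(m2@y, merged@y)
  broken <- west[west@labels$treatment != "T0" | west@labels$date != "d1"]
  expect_error(balancedMerge(east, broken, seed = 1), "cell")
})

test_that("field-replicate aggregation averages sub-units per replicate", {
  cfg <- smallConfig(seed = 2, nDates = 2, blocks = 2)
  resSub <- runPipeline(cfg)
  cfg$scale <- "field_replicate"
  resRep <- runPipeline(cfg)
  expect_equal(resRep$report$n_scale, resSub$report$n_subunit / 3)
  # direct check of the aggregation operation
  ds <- resSub$dataset
  agg <- fieldReplicateScale(ds)
  key <- paste(ds@labels$date, ds@labels$side, ds@labels$replicate_id)
  expect_equal(length(agg), length(unique(key)))
  i <- which(key == key[1])
  j <- which(paste(agg@labels$date, agg@labels$side,
                   agg@labels$replicate_id) == key[1])
  expect_equal(agg@y[j], mean(ds@y[i]))
  expect_equal(as.numeric(agg@X[j, ]), colMeans(ds@X[i, , drop = FALSE]))
})

test_that("the pipeline is bit-reproducible and leak-free", {
  cfg <- smallConfig(seed = 6, nDates = 3, blocks = 2)
  r1 <- runPipeline(cfg)
  r2 <- runPipeline(cfg)
  expect_identical(r1$report, r2$report)
  expect_identical(r1$model@coefficients, r2$model@coefficients)
  # the fitted model never saw external samples: shuffling external y
  # changes Rp2 but not the model
  ext <- r1$external
  shuffled <- ext
  shuffled@y <- rev(ext@y)
  mShuf <- regMetrics(shuffled@y, predictPsi(r1$model, shuffled))
  expect_false(isTRUE(all.equal(mShuf$R2, r1$report$Rp2)))
  expect_identical(r1$model@coefficients, r2$model@coefficients)
})
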