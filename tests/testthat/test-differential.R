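test_that("median-of-ratios size factors match hand computation", {
  ## identical columns -> equal size factors
  m <- matrix(c(5, 5, 9, 9, 30, 30), nrow = 3, byrow = TRUE)
  expect_equal(unname(medianRatioSizeFactors(m)), c(1, 1))

  ## hand-computed: per-gene geomeans sqrt(8), sqrt(18), sqrt(200); every
  ## ratio in column 1 is 1/sqrt(2), in column 2 sqrt(2)
  m2 <- matrix(c(2, 4, 3, 6, 10, 20), nrow = 3, byrow = TRUE)
  expect_equal(unname(medianRatioSizeFactors(m2)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  ## global rescaling of the counts leaves size factors unchanged
  expect_equal(medianRatioSizeFactors(m2 * 7), medianRatioSizeFactors(m2))

  ## no all-positive transcript -> informative error
  m3 <- matrix(c(0, 4, 3, 0), nrow = 2)
  expect_error(medianRatioSizeFactors(m3), "pseudo-reference")
})

test_that("LRT is null for constant transcripts and matches a brute-force grid", {
  tce <- TimecourseExperiment(
    matrix(rep(c(10, 10, 10, 10, 40, 40), each = 1), nrow = 1,
           dimnames = list("Ttoy", NULL)),
    data.frame(time = rep(c("0min", "45min", "24h"), each = 2)))
  sf <- setNames(rep(1, 6), colnames(counts(tce)))

  ## identical counts in every sample: nested models coincide
  flat <- TimecourseExperiment(
    matrix(7, 1, 6, dimnames = list("Tflat", NULL)),
    data.frame(time = rep(c("0min", "45min", "24h"), each = 2)))
  deFlat <- nbLRT(flat, sf, calibration = "chisq")
  expect_lt(deFlat$lrtStat, 1e-6)
  expect_equal(deFlat$pvalue, 1, tolerance = 1e-6)

  ## toy 3-group fit vs independent grid/optimize maximization
  de <- nbLRT(tce, sf, calibration = "chisq")
  pOracle <- oracleNbLrtChisqP(counts(tce)[1, ], rep(1:3, each = 2))
  expect_equal(de$pvalue, pOracle, tolerance = 5e-4)
  expect_equal(unname(c(de$mean_0min, de$mean_45min, de$mean_24h)),
               c(10, 10, 40), tolerance = 1e-3)
})

test_that("LRT output contracts hold on simulated data", {
  sim <- simulateCounts(defaultSimulationDesign(seed = 3, nTranscripts = 300))
  de <- suppressMessages(nbLRT(sim$experiment))
  expect_true(all(de$fdr >= de$pvalue))
  expect_true(all(de$lrtStat >= 0))
  expect_identical(de$isDet, de$fdr < 0.05)

  ## all-zero transcripts are excluded and reported
  m <- counts(sim$experiment)
  m[1:5, ] <- 0
  tce <- TimecourseExperiment(m, data.frame(time = timeLabels(sim$experiment)))
  expect_message(de0 <- nbLRT(tce, medianRatioSizeFactors(tce)), "all-zero")
  expect_setequal(S4Vectors::metadata(de0)$excluded, rownames(m)[1:5])
  expect_false(any(rownames(m)[1:5] %in% de0$transcript))

  ## relabeling samples within their groups leaves the statistics unchanged
  tm <- timeLabels(sim$experiment)
  set.seed(1)
  perm <- unlist(lapply(split(seq_along(tm), tm), sample))
  permuted <- TimecourseExperiment(counts(sim$experiment)[, perm],
                                   data.frame(time = tm[perm]))
  dePerm <- suppressMessages(nbLRT(permuted))
  expect_equal(de$lrtStat, dePerm$lrtStat, tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(71)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, oracleBH(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
  }
})

test_that("VST is monotone, depth-invariant and variance-flattening", {
  m <- matrix(c(0, 10, 100, 1000, 0, 20, 200, 2000), ncol = 2,
              dimnames = list(paste0("T", 1:4), c("a", "b")))
  v <- vstCounts(m, c(a = 1, b = 2))
  expect_equal(v[1, ], c(a = 0, b = 0))             # zeros map to zero
  expect_equal(v[, "a"], v[, "b"])                  # doubled counts + sf
  expect_true(all(diff(v[, "a"]) > 0))              # monotone

  ## decile variances of null transcripts stay within a 10x band
  sim <- simulateCounts(simulationDesign(nTranscripts = 1500,
                                         baselineMean = 200, dispersion = 0.05,
                                         modules = list(), seed = 13))
  expr <- vstCounts(sim$experiment)
  mu <- rowMeans(counts(sim$experiment))
  dec <- cut(rank(mu), 10)
  vdec <- tapply(apply(expr, 1, var), dec, median)
  expect_lt(max(vdec) / min(vdec), 10)
})

test_that("PCA separates the 24h group along the leading component", {
  expr <- matrix(rnorm(50 * 6), 50, 6,
                 dimnames = list(NULL, paste0("S", 1:6)))
  expr[, 6] <- expr[, 5]                            # duplicated sample
  pc <- pcaEmbedding(expr, 3)
  expect_equal(pc$scores["S5", ], pc$scores["S6", ], tolerance = 1e-8)
  expect_true(all(diff(pc$varianceFraction) <= 1e-12))
  expect_lte(sum(pc$varianceFraction), 1 + 1e-12)
  expect_error(pcaEmbedding(expr, 10), "nComponents")

  sim <- simulateCounts(defaultSimulationDesign(seed = 2, nTranscripts = 600))
  pca <- pcaEmbedding(vstCounts(sim$experiment), 2)
  tm <- timeLabels(sim$experiment)
  pc1 <- pca$scores[, 1]
  centroidGap <- abs(mean(pc1[tm == "24h"]) - mean(pc1[tm == "0min"]))
  within <- mean(c(abs(pc1[tm == "24h"] - mean(pc1[tm == "24h"])),
                   abs(pc1[tm == "0min"] - mean(pc1[tm == "0min"]))))
  expect_gt(centroidGap, within)
})

test_that("power analysis reproduces the design's eight mice per group", {
  ## oracle: direct noncentral-F power scan over n = 2..50
  expect_identical(powerSampleSize(0.7, 0.05, 0.8, 3),
                   oraclePowerScan(0.7, 0.05, 0.8, 3))
  expect_equal(powerSampleSize(0.7, 0.05, 0.8, 3), 8)
  ## monotonicity: a larger effect never needs more samples
  ns <- vapply(c(0.3, 0.5, 0.7, 1, 2), powerSampleSize, 0,
               alpha = 0.05, power = 0.8, kGroups = 3)
  expect_true(all(diff(ns) <= 0))
  ## boundary: vanishing power target -> minimum viable n
  expect_equal(powerSampleSize(0.7, 0.05, 1e-9, 3), 2)
})
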