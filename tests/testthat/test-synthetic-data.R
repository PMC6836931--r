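test_that("count simulation is deterministic under a fixed seed", {
  d <- defaultSimulationDesign(seed = 11, nTranscripts = 400)
  s1 <- simulateCounts(d)
  s2 <- simulateCounts(d)
  expect_identical(counts(s1$experiment), counts(s2$experiment))
  expect_identical(trueModuleLabels(s1$truth), trueModuleLabels(s2$truth))

  a1 <- simulateAnnotations(s1$truth, nTerms = 20, seed = 3)
  a2 <- simulateAnnotations(s2$truth, nTerms = 20, seed = 3)
  expect_identical(a1$termMap, a2$termMap)

  t1 <- simulateTfAndPpi(a1$truth, seed = 5)
  t2 <- simulateTfAndPpi(a2$truth, seed = 5)
  expect_identical(graphEdges(t1$graph), graphEdges(t2$graph))
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  d <- simulationDesign(nTranscripts = 200, baselineMean = 100,
                        dispersion = 1e-8, modules = list(), seed = 2)
  sim <- simulateCounts(d)
  m <- counts(sim$experiment)
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_gt(quantile(ratio, 0.05), 0.5)
  expect_lt(quantile(ratio, 0.95), 2)
  expect_equal(median(ratio), 1, tolerance = 0.2)
})

test_that("NB moments follow Var = mu + alpha mu^2 on null transcripts", {
  d <- simulationDesign(nTranscripts = 1000, baselineMean = 200,
                        dispersion = 0.1, modules = list(), seed = 9)
  m <- counts(simulateCounts(d)$experiment)
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  hi <- mu > 100                      # dispersion dominates Poisson noise
  alphaHat <- (v[hi] - mu[hi]) / mu[hi]^2
  expect_equal(median(alphaHat), 0.1, tolerance = 0.35)
})

test_that("planted fold change is recovered by Monte-Carlo averaging", {
  ## oracle: direct MC mean of the 24h/0min ratio over replicate simulations
  ratios <- vapply(1:200, function(s) {
    d <- simulationDesign(
      nTranscripts = 30, baselineMean = 100, dispersion = 0.05,
      modules = list(plantedModule("up", 10, "up_24h", log2Effect = 2,
                                   withinCorrelation = 0)),
      seed = s)
    sim <- simulateCounts(d)
    m <- counts(sim$experiment)
    mod <- names(trueModuleLabels(sim$truth))[trueModuleLabels(sim$truth) == "up"]
    tm <- timeLabels(sim$experiment)
    mean(m[mod, tm == "24h"]) / mean(m[mod, tm == "0min"])
  }, 0)
  expect_equal(mean(ratios), 4, tolerance = 0.2)
})

test_that("oversized module plans are rejected with a sizing error", {
  d <- simulationDesign(nTranscripts = 10,
                        modules = list(plantedModule("big", 20, "up_24h")))
  expect_error(simulateCounts(d), "exceeds nTranscripts")
})

test_that("profile shapes act on the intended groups", {
  d <- simulationDesign(
    nTranscripts = 120, baselineMean = 500, dispersion = 0.01,
    modules = list(
      plantedModule("t45", 20, "transient_45min", 2, 0),
      plantedModule("dn", 20, "down_24h", 2, 0)),
    seed = 4)
  sim <- simulateCounts(d)
  m <- counts(sim$experiment)
  tm <- timeLabels(sim$experiment)
  lab <- trueModuleLabels(sim$truth)
  t45 <- names(lab)[lab == "t45"]
  dn <- names(lab)[lab == "dn"]
  ## transient: middle group elevated, flanks comparable
  expect_gt(mean(m[t45, tm == "45min"]) / mean(m[t45, tm == "0min"]), 2.5)
  expect_equal(mean(m[t45, tm == "24h"]) / mean(m[t45, tm == "0min"]), 1,
               tolerance = 0.35)
  ## down at 24h: negative sign applied
  expect_lt(mean(m[dn, tm == "24h"]) / mean(m[dn, tm == "0min"]), 0.5)
  ## truth differential set is the union of the non-null modules
  expect_setequal(trueDeTranscripts(sim$truth), c(t45, dn))
})

test_that("annotation generator plants terms inside modules", {
  sim <- simulateCounts(defaultSimulationDesign(seed = 6, nTranscripts = 400))
  ## noiseRate 0: planted term gene sets are subsets of their module
  ann0 <- simulateAnnotations(sim$truth, nTerms = 12, noiseRate = 0,
                              plantedPerModule = 1, seed = 1)
  lab <- trueModuleLabels(sim$truth)
  planted <- ann0$termMap[grepl("^GO:P", names(ann0$termMap))]
  for (tm in planted) expect_length(unique(lab[tm]), 1)
  ## every term has >= 3 genes and exactly one category entry
  ann <- simulateAnnotations(sim$truth, nTerms = 30, noiseRate = 0.2, seed = 2)
  expect_true(all(lengths(ann$termMap) >= 3))
  expect_setequal(names(ann$categoryMap), names(ann$termMap))
  expect_false(anyDuplicated(names(ann$categoryMap)) > 0)
  ## too few terms for the planted modules
  expect_error(simulateAnnotations(sim$truth, nTerms = 2), "at least")
})

test_that("planted terms give astronomically small enrichment p-values", {
  sim <- simulateCounts(simulationDesign(
    nTranscripts = 2000,
    modules = list(plantedModule("m1", 50, "up_24h")), seed = 8))
  ann <- simulateAnnotations(sim$truth, nTerms = 10, noiseRate = 0,
                             plantedPerModule = 1, termSize = 20, seed = 1)
  lab <- trueModuleLabels(sim$truth)
  mod <- names(lab)[lab == "m1"]
  rec <- hypergeomEnrich(mod, ann$termMap, names(lab))
  planted <- rec[grepl("^GO:P", rec$term), ]
  expect_lt(planted$pvalue, 1e-10)
  ## agrees with the exact tail-sum oracle
  expect_equal(planted$pvalue,
               oracleHyperTail(planted$x, planted$termSize, 50, 2000),
               tolerance = 1e-12)
})

test_that("TF/PPI generator separates driven from background TFs", {
  sim <- simulateCounts(defaultSimulationDesign(seed = 10, nTranscripts = 1000))
  ann <- simulateAnnotations(sim$truth, nTerms = 30, seed = 2)
  tp <- simulateTfAndPpi(ann$truth, nTfs = 20, seed = 3)
  truth <- tp$truth
  de <- trueDeTranscripts(truth)
  bg <- setdiff(names(trueModuleLabels(truth)), de)
  rec <- tfOverrepresentation(de, bg, tp$tfTargets)
  drivenF <- rec$fScore[rec$tf %in% truth@drivenTfs]
  backgroundF <- rec$fScore[!rec$tf %in% truth@drivenTfs]
  expect_gt(min(drivenF), max(backgroundF))

  ## hub is reachable from the driven-TF seed set within two expansion steps
  g <- igraph::graph_from_data_frame(graphEdges(tp$graph), directed = FALSE)
  dmat <- igraph::distances(g, v = truth@drivenTfs, to = trueHubNode(truth))
  expect_true(all(dmat <= 2))

  ## edge confidences live in (0, 1]
  expect_true(all(graphEdges(tp$graph)$confidence > 0 &
                  graphEdges(tp$graph)$confidence <= 1))
  expect_error(simulateTfAndPpi(ann$truth, nTfs = 3), ">= 5")
})
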