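toyGraph <- function() {
  InteractionGraph(data.frame(
    from = c("A", "A", "B", "C"),
    to = c("B", "C", "D", "E"),
    confidence = c(0.9, 0.5, 0.8, 0.4)))
}

test_that("greedy expansion reproduces the hand-traced example", {
  g <- toyGraph()
  tr <- expandNetwork(g, "A", schedule = c(2))
  ## B first (0.9 > 0.5), then D (0.8 via B beats C's 0.5)
  expect_setequal(layerNodeSets(tr)[[2]], c("A", "B", "D"))

  ## zero-step schedule leaves the network unchanged
  tr0 <- expandNetwork(g, "A", schedule = c(0))
  expect_identical(layerNodeSets(tr0)[[2]], layerNodeSets(tr0)[[1]])

  ## seeding with the whole graph saturates immediately
  trAll <- expandNetwork(g, graphNodes(g), schedule = c(5, 5))
  expect_true(trAll@saturated)
  expect_identical(layerNodeSets(trAll)[[3]], layerNodeSets(trAll)[[1]])

  expect_error(expandNetwork(g, character(0)), "non-empty")
  expect_error(expandNetwork(g, "ZZ"), "belong")
})

test_that("expansion is deterministic and nested on random graphs", {
  set.seed(17)
  for (i in 1:10) {
    n <- 40
    e <- data.frame(from = sprintf("N%02d", sample(n, 80, TRUE)),
                    to = sprintf("N%02d", sample(n, 80, TRUE)),
                    confidence = runif(80, 0.1, 1))
    e <- e[e$from != e$to, ]
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    g <- InteractionGraph(e[!duplicated(key), ])
    seeds <- sample(graphNodes(g), 3)
    t1 <- expandNetwork(g, seeds, schedule = c(3, 3, 5))
    t2 <- expandNetwork(g, seeds, schedule = c(3, 3, 5))
    expect_identical(layerNodeSets(t1), layerNodeSets(t2))
    ns <- layerNodeSets(t1)
    for (l in seq_along(ns)[-1]) expect_true(all(ns[[l - 1]] %in% ns[[l]]))
    gr <- growthPercent(t1)
    expect_true(all(diff(gr) >= 0))
    expect_equal(gr[1], 0)
  }
})

test_that("tie-breaking prefers confidence, then degree, then id", {
  ## two candidates with equal summed confidence: higher-degree node wins
  g <- InteractionGraph(data.frame(
    from = c("S", "S", "Y", "Y"),
    to = c("X", "Y", "P", "Q"),
    confidence = c(0.6, 0.6, 0.3, 0.3)))
  tr <- expandNetwork(g, "S", schedule = c(1))
  expect_setequal(layerNodeSets(tr)[[2]], c("S", "Y"))
  ## equal confidence and degree: lexicographically smaller id
  g2 <- InteractionGraph(data.frame(
    from = c("S", "S"), to = c("B", "A"), confidence = c(0.5, 0.5)))
  tr2 <- expandNetwork(g2, "S", schedule = c(1))
  expect_setequal(layerNodeSets(tr2)[[2]], c("A", "S"))
})

test_that("network GO profile flags unmapped and empty node sets", {
  uni <- paste0("g", 1:50)
  termMap <- list(T1 = paste0("g", 1:10), T2 = paste0("g", 30:45))
  expect_message(terms <- networkGoProfile(c(paste0("g", 1:10), "XX"),
                                           termMap, uni),
                 "dropped")
  expect_identical(terms, "T1")
  expect_warning(empty <- networkGoProfile("XX", termMap, uni), "universe")
  expect_identical(empty, character(0))
})

test_that("sensitivity, specificity and growth follow set arithmetic", {
  expect_equal(sensitivitySpecificity(c("a", "b"), c("a", "b")),
               c(sensitivity = 100, specificity = 100))
  expect_equal(sensitivitySpecificity(c("x"), c("a", "b")),
               c(sensitivity = 0, specificity = 0))
  ss <- sensitivitySpecificity(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_equal(unname(ss), c(50, 200 / 3), tolerance = 1e-10)
  expect_equal(sensitivitySpecificity(character(0), c("a")),
               c(sensitivity = 0, specificity = 0))
  expect_error(sensitivitySpecificity("a", character(0)), "non-empty")

  tr <- new("GrowthTrajectory", tfGroup = 1L,
            nodeSets = list(paste0("n", 1:10), paste0("n", 1:25)),
            saturated = FALSE, stats = data.frame())
  expect_equal(growthPercent(tr), c(0, 150))
})

## hand-built profiled trajectories for the selection rule
fakeTrajectory <- function(group, stats) {
  ## nested node sets of the sizes recorded in the stats table
  nodeSets <- lapply(stats$nNodes, function(k) sprintf("n%d_%02d", group, 1:k))
  new("GrowthTrajectory", tfGroup = as.integer(group),
      nodeSets = nodeSets, saturated = FALSE,
      stats = cbind(group = group, layer = seq_len(nrow(stats)) - 1L, stats))
}

test_that("network selection applies thresholds then maximizes specificity", {
  t1 <- fakeTrajectory(1, data.frame(
    nNodes = c(4, 10, 16, 24), nTerms = 1:4,
    sensitivity = c(10, 30, 45, 60), specificity = c(90, 80, 60, 30),
    growth = c(0, 150, 300, 500)))
  ## only layers 2 and 3 pass sens >= 40; layer 2 has higher specificity
  sel <- selectNetwork(list(t1))
  expect_equal(sel$layer, 2)
  expect_false(sel$relaxed)
  expect_length(sel$nodes, 16)

  ## two qualifying candidates across groups: specificity 60 beats 45
  t2 <- fakeTrajectory(2, data.frame(
    nNodes = c(5, 20), nTerms = 1:2,
    sensitivity = c(50, 55), specificity = c(45, 20),
    growth = c(200, 400)))
  sel2 <- selectNetwork(list(t1, t2))
  expect_equal(sel2$tfGroup, 1)
  expect_equal(sel2$row$specificity, 60)

  ## no qualifying layer: relaxed fallback to maximal sensitivity
  t3 <- fakeTrajectory(3, data.frame(
    nNodes = c(4, 8), nTerms = 1:2,
    sensitivity = c(10, 35), specificity = c(90, 80),
    growth = c(0, 100)))
  sel3 <- selectNetwork(list(t3))
  expect_true(sel3$relaxed)
  expect_equal(sel3$layer, 1)
})

test_that("k-means partition ranks tiers by connectivity", {
  ## star graph: the hub must land in the core tier
  star <- InteractionGraph(data.frame(
    from = "HUB", to = sprintf("L%02d", 1:12), confidence = 0.8))
  lab <- partitionNetworkKmeans(graphNodes(star), star, k = 3, seed = 2)
  expect_identical(unname(lab["HUB"]), "core")
  expect_false(any(lab[names(lab) != "HUB"] == "core"))
  ## determinism under the same seed
  lab2 <- partitionNetworkKmeans(graphNodes(star), star, k = 3, seed = 2)
  expect_identical(lab, lab2)
  expect_error(partitionNetworkKmeans(c("HUB", "L01"), star, k = 3),
               "exceeds")

  ## three planted degree tiers are recovered
  core <- sprintf("C%d", 1:4)
  mid <- sprintf("M%02d", 1:8)
  leaf <- sprintf("P%02d", 1:16)
  corePairs <- t(combn(core, 2))
  e <- rbind(
    data.frame(from = corePairs[, 1], to = corePairs[, 2], confidence = 0.9),
    expand.grid(from = mid, to = core, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE) |> transform(confidence = 0.6),
    data.frame(from = leaf, to = rep(mid, 2), confidence = 0.3))
  g <- InteractionGraph(e)
  tiers <- partitionNetworkKmeans(graphNodes(g), g, k = 3, seed = 4)
  truth <- rep(c("core", "secondary", "peripheral"), c(4, 8, 16))
  names(truth) <- c(core, mid, leaf)
  expect_gte(oracleARI(tiers[names(truth)], truth), 0.8)
})
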