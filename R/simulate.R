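#' Simulate a negative-binomial surgical time course with planted modules
#'
#' Counts are drawn as NB(mu, alpha) with Var = mu + alpha mu^2.  Per-module
#' temporal effects are applied multiplicatively on the group means
#' (\code{2^log2Effect} on the profile's active group; \code{down_24h} uses
#' the negative sign).  Within-module correlation is induced by a shared
#' per-sample latent factor f ~ N(0,1): mu_gj = base_g * effect_gj *
#' exp(w * f_j) with w = withinCorrelation.  Surgeon and batch columns are
#' generated; by default they carry no effect (set
#' \code{batchLog2Effect != 0} for PCA QC experiments).
#'
#' @param design a \linkS4class{SimulationDesign}
#' @return list with \code{experiment} (a
#'   \linkS4class{TimecourseExperiment}) and \code{truth} (a
#'   \linkS4class{GroundTruth} carrying module labels and the true
#'   differential set)
#' @examples
#' sim <- simulateCounts(defaultSimulationDesign(seed = 7, nTranscripts = 300))
#' dim(counts(sim$experiment))
#' @export
simulateCounts <- function(design) {
  stopifnot(is(design, "SimulationDesign"))
  validObject(design)
  nT <- design@nTranscripts
  sizes <- vapply(design@modules, function(m) m@size, 0L)
  if (sum(sizes) > nT)
    stop("planted module sizes sum to ", sum(sizes),
         " which exceeds nTranscripts = ", nT)
  set.seed(design@seed)
  groups <- design@groups
  nG <- length(groups)
  nS <- nG * design@nPerGroup
  ids <- sprintf("T%05d", seq_len(nT))
  time <- factor(rep(groups, each = design@nPerGroup), levels = groups)
  surgeon <- rep_len(c("S1", "S2"), nS)
  batch <- paste0("B", rep_len(1:4, nS))
  sampleIds <- sprintf("%s_r%d", time, sequence(rep(design@nPerGroup, nG)))

  ## per-transcript baseline means around the design baseline
  base <- exp(stats::rnorm(nT, log(design@baselineMean), 0.7))

  ## module membership: consecutive blocks, disjoint by construction
  labels <- rep("unassigned", nT)
  at <- 1L
  for (m in design@modules) {
    labels[at:(at + m@size - 1L)] <- m@name
    at <- at + m@size
  }
  names(labels) <- ids

  ## log2 effect per module x group
  logMu <- matrix(log(base), nT, nS)
  midGroup <- groups[ceiling((nG + 1) / 2)]
  lastGroup <- groups[nG]
  for (m in design@modules) {
    rows <- which(labels == m@name)
    eff <- stats::setNames(numeric(nG), groups)
    if (m@profile == "transient_45min") eff[midGroup] <- m@log2Effect
    if (m@profile == "up_24h") eff[lastGroup] <- m@log2Effect
    if (m@profile == "down_24h") eff[lastGroup] <- -abs(m@log2Effect)
    logMu[rows, ] <- logMu[rows, ] +
      matrix(rep(eff[as.character(time)] * log(2), each = length(rows)),
             nrow = length(rows))
    ## shared latent factor: one value per sample, common to the module
    f <- stats::rnorm(nS)
    logMu[rows, ] <- logMu[rows, ] +
      matrix(rep(m@withinCorrelation * f, each = length(rows)),
             nrow = length(rows))
  }
  if (design@batchLog2Effect != 0) {
    bEff <- (as.integer(factor(batch)) - mean(as.integer(factor(batch)))) *
      design@batchLog2Effect * log(2)
    logMu <- logMu + matrix(rep(bEff, each = nT), nT)
  }

  mu <- exp(logMu)
  cnt <- matrix(stats::rnbinom(nT * nS, mu = mu, size = 1 / design@dispersion),
                nT, nS, dimnames = list(ids, sampleIds))
  exper <- TimecourseExperiment(
    cnt, data.frame(time = time, surgeon = surgeon, batch = batch),
    timeLevels = groups)
  deNames <- unlist(lapply(design@modules, function(m)
    if (m@profile != "null") names(labels)[labels == m@name] else character(0)))
  truth <- new("GroundTruth", moduleLabels = labels,
               deTranscripts = as.character(deNames))
  list(experiment = exper, truth = truth)
}

#' Simulate GO-style annotations concentrated in the planted modules
#'
#' For each planted module, \code{plantedPerModule} "planted" terms are
#' created whose gene sets are drawn for a fraction \code{1 - noiseRate}
#' from that module (and for \code{noiseRate} from the background); the
#' remaining terms are uniform background.  Every term receives one process
#' category; planted terms get the category matching their module's temporal
#' role.
#'
#' @param truth a \linkS4class{GroundTruth} from \code{\link{simulateCounts}}
#' @param nTerms total number of terms (must be >= number of planted modules)
#' @param noiseRate fraction in [0,1] of a planted term's genes drawn outside
#'   its module (keep <= 0.3 so planted terms stay >= 70 percent in-module)
#' @param plantedPerModule planted terms per module (default 2)
#' @param termSize genes per planted term (default 20)
#' @param seed RNG seed
#' @return list with \code{termMap} (named list term -> genes),
#'   \code{categoryMap} (named character term -> category) and the updated
#'   \code{truth}
#' @export
simulateAnnotations <- function(truth, nTerms = 60, noiseRate = 0.2,
                                plantedPerModule = 2, termSize = 20,
                                seed = 1) {
  stopifnot(is(truth, "GroundTruth"))
  if (noiseRate < 0 || noiseRate > 1) stop("noiseRate must be in [0,1]")
  moduleNames <- setdiff(unique(truth@moduleLabels), "unassigned")
  if (nTerms < length(moduleNames))
    stop("nTerms must be at least the number of planted modules (",
         length(moduleNames), ")")
  set.seed(seed)
  universe <- names(truth@moduleLabels)
  categories <- c("cell signalization", "tissue regeneration",
                  "inflammatory and immune response", "cell migration",
                  "metabolism", "cell death", "vasculature remodeling")
  moduleCat <- stats::setNames(
    rep_len(c("cell signalization", "inflammatory and immune response",
              "metabolism"), length(moduleNames)), moduleNames)
  termMap <- list()
  categoryMap <- character(0)
  k <- 0L
  for (mod in moduleNames) {
    members <- names(truth@moduleLabels)[truth@moduleLabels == mod]
    outside <- setdiff(universe, members)
    for (j in seq_len(plantedPerModule)) {
      k <- k + 1L
      id <- sprintf("GO:P%03d", k)
      nIn <- max(3L, round(termSize * (1 - noiseRate)))
      nIn <- min(nIn, length(members))
      nOut <- min(termSize - nIn, length(outside))
      termMap[[id]] <- sort(c(sample(members, nIn),
                              if (nOut > 0) sample(outside, nOut)))
      categoryMap[id] <- moduleCat[[mod]]
    }
  }
  nBg <- nTerms - k
  for (j in seq_len(max(0L, nBg))) {
    id <- sprintf("GO:B%03d", j)
    sz <- sample(10:40, 1)
    termMap[[id]] <- sort(sample(universe, min(sz, length(universe))))
    categoryMap[id] <- sample(categories, 1)
  }
  small <- lengths(termMap) < 3L
  termMap <- termMap[!small]
  categoryMap <- categoryMap[names(termMap)]
  truth@termMap <- termMap
  truth@categoryMap <- categoryMap
  list(termMap = termMap, categoryMap = categoryMap, truth = truth)
}

#' Simulate TF target sets and a PPI graph with a planted upstream hub
#'
#' A subset of TFs ("driven") get target sets concentrated in the planted
#' differential transcripts (preferentially the planted GO-term genes of one
#' module each); the remaining TFs draw targets uniformly.  The PPI graph
#' wires a hub node to the driven TFs through a short signalling cascade,
#' connects driven TFs to their planted targets with high-confidence edges,
#' adds within-term gene-gene edges, and surrounds everything with random
#' low-confidence background.  An "upstream signalization" annotation term
#' covering hub, cascade and driven TFs is appended to the truth's term map.
#'
#' @param truth a \linkS4class{GroundTruth} that already carries annotations
#' @param nTfs number of TFs (>= 5)
#' @param nBackgroundNodes number of unrelated background proteins
#' @param seed RNG seed
#' @param drivenFraction fraction of TFs that are planted drivers
#' @param targetSize targets per TF
#' @param drivenEnrichment fraction of a driven TF's targets drawn from its
#'   module's planted-term genes
#' @return list with \code{tfTargets}, \code{graph}
#'   (\linkS4class{InteractionGraph}) and the updated \code{truth}
#' @export
simulateTfAndPpi <- function(truth, nTfs = 24, nBackgroundNodes = 120,
                             seed = 1, drivenFraction = 1 / 3,
                             targetSize = 30, drivenEnrichment = 0.8) {
  stopifnot(is(truth, "GroundTruth"))
  if (nTfs < 5) stop("nTfs must be >= 5")
  set.seed(seed)
  universe <- names(truth@moduleLabels)
  moduleNames <- setdiff(unique(truth@moduleLabels), "unassigned")
  plantedTerms <- truth@termMap[grepl("^GO:P", names(truth@termMap))]
  ## planted-term genes grouped by module
  termGenesByModule <- lapply(moduleNames, function(mod) {
    members <- names(truth@moduleLabels)[truth@moduleLabels == mod]
    sort(unique(intersect(unlist(plantedTerms), members)))
  })
  names(termGenesByModule) <- moduleNames

  tfIds <- sprintf("TF%02d", seq_len(nTfs))
  nDriven <- max(2L, round(nTfs * drivenFraction))
  driven <- tfIds[seq_len(nDriven)]
  tfTargets <- list()
  edges <- list()
  for (i in seq_len(nTfs)) {
    tf <- tfIds[i]
    if (i <= nDriven && length(moduleNames)) {
      mod <- moduleNames[((i - 1L) %% length(moduleNames)) + 1L]
      pool <- termGenesByModule[[mod]]
      if (!length(pool)) pool <- truth@deTranscripts
      nIn <- min(round(targetSize * drivenEnrichment), length(pool))
      tgt <- c(sample(pool, nIn),
               sample(setdiff(universe, pool), targetSize - nIn))
      ## high-confidence edges from the TF to its planted targets
      link <- sample(tgt[tgt %in% pool], min(12L, nIn))
      edges[[tf]] <- data.frame(
        from = tf, to = link,
        confidence = stats::runif(length(link), 0.75, 0.95))
    } else {
      tgt <- sample(universe, targetSize)
      link <- sample(tgt, 5L)
      edges[[tf]] <- data.frame(
        from = tf, to = link,
        confidence = stats::runif(length(link), 0.10, 0.40))
    }
    tfTargets[[tf]] <- sort(tgt)
  }

  ## pleiotropic hub: wired directly to every driven TF (cytokine-style
  ## effector activation) and through a receptor/transducer cascade node
  hub <- "HUB1"
  sig <- "SIG1"
  cascade <- c(hub, sig)
  edges[["hub"]] <- data.frame(
    from = c(hub, rep(sig, nDriven), rep(hub, nDriven)),
    to = c(sig, driven, driven),
    confidence = c(0.99, rep(0.95, nDriven),
                   stats::runif(nDriven, 0.85, 0.95)))

  ## within-term gene-gene edges (co-complex style)
  gg <- list()
  for (tn in names(plantedTerms)) {
    g <- plantedTerms[[tn]]
    if (length(g) < 2) next
    pairs <- utils::combn(sort(g), 2)
    keep <- stats::runif(ncol(pairs)) < 0.15
    if (!any(keep)) next
    gg[[tn]] <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                           confidence = stats::runif(sum(keep), 0.35, 0.65))
  }

  ## background proteins with sparse random wiring
  bg <- sprintf("BG%03d", seq_len(nBackgroundNodes))
  others <- c(bg, sample(universe, min(50, length(universe))))
  nbe <- 2L * nBackgroundNodes
  bgE <- data.frame(from = sample(bg, nbe, replace = TRUE),
                    to = sample(others, nbe, replace = TRUE),
                    confidence = stats::runif(nbe, 0.05, 0.40))
  bgE <- bgE[bgE$from != bgE$to, ]

  allE <- do.call(rbind, c(edges, gg, list(bgE)))
  key <- paste(pmin(allE$from, allE$to), pmax(allE$from, allE$to))
  allE <- allE[!duplicated(key), ]
  graph <- InteractionGraph(allE, nodes = c(tfIds, hub, sig, bg))

  ## annotate the planted upstream machinery
  upstream <- sort(c(hub, sig, driven))
  truth@termMap[["GO:UPSTREAM"]] <- upstream
  truth@categoryMap["GO:UPSTREAM"] <- "upstream signalization"
  truth@tfTargets <- tfTargets
  truth@drivenTfs <- driven
  truth@hubNode <- hub
  truth@cascade <- cascade
  list(tfTargets = tfTargets, graph = graph, truth = truth)
}
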