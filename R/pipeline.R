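#' Default pipeline configuration
#'
#' Every decision threshold of the analysis lives here: DET FDR 0.05, GO-term
#' FDR 1e-4 (strict), module z cutoff 2, TF F-score cutoff 20, the five
#' nested |z| cuts 35/25/15/10/2, network sensitivity 40 percent, growth 150
#' percent, and the default growth schedule 5, 5, 10, 10, 10 (cumulative
#' +5/+10/+20/+30/+40 nodes).
#'
#' @param seed RNG seed used for simulation and k-means
#' @return nested configuration list; a \code{simulate} block requests the
#'   synthetic study, otherwise \code{paths} must name the input files
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(nTranscripts = 2000, nTerms = 60, noiseRate = 0.2,
                    nTfs = 24, nBackgroundNodes = 120),
    detFdr = 0.05,
    termFdrMax = 1e-4,
    zMin = 2,
    fMin = 20,
    zCuts = c(35, 25, 15, 10, 2),
    sensMin = 40,
    growthMin = 150,
    schedule = c(5, 5, 10, 10, 10),
    eq1VarianceFactor = 1,
    softPower = list(candidates = 1:30, fitTarget = 0.8),
    minModuleSize = 20,
    cutHeight = 0.99,
    maxCombinedModules = 3)
}

## merge user overrides into the default config (shallow per key)
.mergeConfig <- function(config) {
  base <- defaultPipelineConfig(seed = if (!is.null(config$seed)) config$seed else 1)
  for (k in names(config)) base[[k]] <- config[[k]]
  base
}

.writeTsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full retro-analysis pipeline
#'
#' Sequences simulation (or file input), differential expression, PCA QC,
#' co-expression module detection, GO enrichment with module combinations,
#' TF over-representation and grouping, layered PPI network growth,
#' network selection and core/secondary/peripheral partitioning.  Stage
#' outputs are written under \code{outDir} (when given) together with a
#' \code{manifest.json} echoing the configuration, seed and per-stage record
#' counts; runs are idempotent for a fixed config and seed.
#'
#' @param config configuration list (see \code{\link{defaultPipelineConfig}})
#'   or path to a YAML file with the same structure
#' @param outDir optional output directory (created if missing)
#' @return invisible list with every stage result (\code{experiment},
#'   \code{truth}, \code{deTable}, \code{pca}, \code{partition},
#'   \code{eigengenes}, \code{detTerms}, \code{groupEnrichment},
#'   \code{bestPredictor}, \code{rollup}, \code{tfTable}, \code{tfGroups},
#'   \code{trajectories}, \code{selection}, \code{tiers}, \code{manifest})
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(config)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  ## ---- stage 0: inputs -----------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sb <- cfg$simulate
    design <- defaultSimulationDesign(
      seed = cfg$seed,
      nTranscripts = if (!is.null(sb$nTranscripts)) sb$nTranscripts else 2000)
    sim <- simulateCounts(design)
    exper <- sim$experiment
    ann <- simulateAnnotations(
      sim$truth,
      nTerms = if (!is.null(sb$nTerms)) sb$nTerms else 60,
      noiseRate = if (!is.null(sb$noiseRate)) sb$noiseRate else 0.2,
      seed = cfg$seed + 1L)
    tp <- simulateTfAndPpi(
      ann$truth,
      nTfs = if (!is.null(sb$nTfs)) sb$nTfs else 24,
      nBackgroundNodes = if (!is.null(sb$nBackgroundNodes)) sb$nBackgroundNodes else 120,
      seed = cfg$seed + 2L)
    truth <- tp$truth
    termMap <- truth@termMap
    categoryMap <- truth@categoryMap
    tfTargets <- tp$tfTargets
    graph <- tp$graph
  } else {
    p <- cfg$paths
    for (f in unlist(p)) if (!is.null(f) && !file.exists(f))
      stop("missing input file: ", f)
    exper <- readCounts(p$counts, p$meta, p$countsRowNames, p$countsColNames)
    termMap <- readGeneSets(p$gmt)
    categoryMap <- readCategoryMap(p$categories)
    tfTargets <- readGeneSets(p$tfTargets)
    graph <- readEdgeList(p$edges)
  }

  ## ---- stage 1: differential expression ------------------------------------
  sf <- medianRatioSizeFactors(exper)
  deTable <- suppressMessages(nbLRT(exper, sf, detFdr = cfg$detFdr))
  dets <- detTranscripts(deTable)
  tested <- deTable$transcript
  .writeTsv(as.data.frame(deTable), outDir, "de_table.tsv")

  expr <- vstCounts(exper, sf)
  pca <- pcaEmbedding(expr, nComponents = 2)
  if (!is.null(outDir))
    .writeTsv(data.frame(sample = rownames(pca$scores), pca$scores,
                         time = as.character(timeLabels(exper))),
              outDir, "pca_scores.tsv")

  ## ---- stage 2: co-expression modules --------------------------------------
  partition <- NULL
  eig <- NULL
  softBeta <- NA
  if (length(dets) >= 20) {
    dexpr <- expr[dets, , drop = FALSE]
    sp <- tryCatch(
      pickSoftThreshold(dexpr, candidates = cfg$softPower$candidates,
                        fitTarget = cfg$softPower$fitTarget),
      error = function(e) list(beta = max(cfg$softPower$candidates),
                               warningFlag = TRUE))
    softBeta <- sp$beta
    tom <- adjacencyTom(dexpr, sp$beta)
    partition <- detectModules(tom, minModuleSize = cfg$minModuleSize,
                               cutHeight = cfg$cutHeight)
    if (length(moduleSizes(partition)))
      eig <- moduleEigengenes(dexpr, partition, time = timeLabels(exper))
    .writeTsv(data.frame(transcript = names(moduleLabels(partition)),
                         module = moduleLabels(partition)),
              outDir, "partition.tsv")
    if (!is.null(eig)) {
      .writeTsv(data.frame(module = rownames(eig$eigengenes),
                           eig$eigengenes, check.names = FALSE),
                outDir, "eigengenes.tsv")
      .writeTsv(data.frame(module = rownames(eig$groupMeans),
                           eig$groupMeans, check.names = FALSE),
                outDir, "profiles.tsv")
    }
  }

  ## ---- stage 3: GO enrichment ----------------------------------------------
  detTerms <- character(0)
  detEnrichment <- NULL
  if (length(dets)) {
    detEnrichment <- hypergeomEnrich(dets, termMap, tested)
    detTerms <- filterTerms(detEnrichment, cfg$termFdrMax)$term
    .writeTsv(detEnrichment, outDir, "det_go.tsv")
  }
  groupEnrichment <- NULL
  bestPredictor <- NULL
  rollup <- NULL
  if (!is.null(partition) && length(moduleSizes(partition)) && length(dets)) {
    ## combine the modules with the most enriched terms (up to the cap)
    modIds <- names(moduleSizes(partition))
    perModule <- lapply(modIds, function(mid)
      moduleMembers(partition, as.integer(mid)))
    names(perModule) <- modIds
    single <- moduleGroupEnrichment(
      stats::setNames(perModule, sprintf("[%s]", modIds)), dets, termMap,
      cfg$termFdrMax, cfg$zMin, cfg$eq1VarianceFactor)
    nEnr <- vapply(modIds, function(mid)
      sum(single$enriched[single$group == sprintf("[%s]", mid)]), 0L)
    top <- modIds[order(-nEnr, as.integer(modIds))]
    top <- top[seq_len(min(length(top), cfg$maxCombinedModules))]
    combos <- enumerateModuleGroups(perModule[top])
    groupEnrichment <- moduleGroupEnrichment(
      combos, dets, termMap, cfg$termFdrMax, cfg$zMin, cfg$eq1VarianceFactor)
    enr <- groupEnrichment[groupEnrichment$enriched, , drop = FALSE]
    bestPredictor <- bestPredictorAssignment(enr)
    rollup <- rollupProcesses(unique(enr$term), categoryMap)
    .writeTsv(groupEnrichment, outDir, "group_go.tsv")
    .writeTsv(rollup$table, outDir, "process_rollup.tsv")
  }

  ## ---- stage 4: TF over-representation -------------------------------------
  tfTable <- NULL
  tfGroups <- stats::setNames(vector("list", length(cfg$zCuts)),
                              paste0("group", seq_along(cfg$zCuts)))
  if (length(dets) && length(setdiff(tested, dets))) {
    tfTable <- tfOverrepresentation(dets, setdiff(tested, dets), tfTargets)
    fg <- filterAndGroupTfs(tfTable, fMin = cfg$fMin, zCuts = cfg$zCuts)
    tfGroups <- fg$groups
    .writeTsv(fg$records, outDir, "tf_table.tsv")
  }

  ## ---- stage 5: network retro-analysis -------------------------------------
  annotUniverse <- unique(c(tested, unlist(termMap)))
  trajectories <- list()
  selection <- NULL
  tiers <- NULL
  if (length(detTerms)) {
    for (g in seq_along(tfGroups)) {
      seeds <- intersect(tfGroups[[g]], graphNodes(graph))
      if (!length(seeds)) next
      tr <- expandNetwork(graph, seeds, schedule = cfg$schedule, tfGroup = g)
      tr <- profileTrajectory(tr, termMap, annotUniverse, detTerms,
                              cfg$termFdrMax)
      trajectories[[length(trajectories) + 1L]] <- tr
    }
    if (length(trajectories)) {
      allStats <- do.call(rbind, lapply(trajectories, layerStats))
      .writeTsv(allStats, outDir, "network_stats.tsv")
      selection <- selectNetwork(trajectories, cfg$sensMin, cfg$growthMin)
      if (length(selection$nodes) >= 3)
        tiers <- partitionNetworkKmeans(selection$nodes, graph, k = 3,
                                        seed = cfg$seed)
      if (!is.null(outDir)) {
        jsonlite::write_json(
          list(tfGroup = selection$tfGroup, layer = selection$layer,
               relaxed = selection$relaxed, nodes = selection$nodes),
          file.path(outDir, "selection.json"), auto_unbox = TRUE)
        if (!is.null(tiers))
          .writeTsv(data.frame(node = names(tiers), tier = unname(tiers)),
                    outDir, "network_tiers.tsv")
      }
    }
  }

  ## ---- manifest ------------------------------------------------------------
  manifest <- list(
    config = cfg[setdiff(names(cfg), "paths")],
    counts = list(
      transcripts = nrow(counts(exper)), samples = ncol(counts(exper)),
      nonZeroTranscripts = length(tested)),
    detCount = length(dets),
    softBeta = softBeta,
    moduleSizes = if (!is.null(partition)) as.list(moduleSizes(partition)) else list(),
    unassignedPercent = if (!is.null(partition)) unassignedPercent(partition) else NA,
    detTermCount = length(detTerms),
    enrichedGroupTermCount = if (!is.null(groupEnrichment))
      sum(groupEnrichment$enriched) else 0L,
    tfGroupSizes = lapply(tfGroups, length),
    selected = if (!is.null(selection))
      list(tfGroup = selection$tfGroup, layer = selection$layer,
           relaxed = selection$relaxed) else NULL)
  if (!is.null(outDir))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(experiment = exper, truth = truth, sizeFactors = sf,
                 deTable = deTable, dets = dets, pca = pca,
                 partition = partition, eigengenes = eig,
                 detEnrichment = detEnrichment, detTerms = detTerms,
                 groupEnrichment = groupEnrichment,
                 bestPredictor = bestPredictor, rollup = rollup,
                 tfTable = tfTable, tfGroups = tfGroups,
                 trajectories = trajectories, selection = selection,
                 tiers = tiers, termMap = termMap, categoryMap = categoryMap,
                 graph = graph, manifest = manifest))
}
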