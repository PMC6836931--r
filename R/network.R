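#' Grow a TF-seeded PPI subnetwork layer by layer
#'
#' Starting from the seed set (layer 0, the "initial network"), each
#' schedule step adds the given number of nodes one at a time, always taking
#' the external node with the largest summed edge confidence towards the
#' current network; ties break towards higher graph-wide degree, then the
#' lexicographically smaller id.  When no external neighbour remains the
#' trajectory saturates: the remaining layers repeat the final set and the
#' \code{saturated} flag is raised.
#'
#' @param graph an \linkS4class{InteractionGraph}
#' @param seedNodes non-empty character vector of seed node ids
#' @param schedule positive integers: nodes added per layer (default
#'   5, 5, 10, 10, 10, i.e. cumulative totals 5/10/20/30/40)
#' @param tfGroup optional TF group index stored on the trajectory
#' @return a \linkS4class{GrowthTrajectory}
#' @export
expandNetwork <- function(graph, seedNodes, schedule = c(5, 5, 10, 10, 10),
                          tfGroup = NA_integer_) {
  stopifnot(is(graph, "InteractionGraph"))
  seedNodes <- unique(as.character(seedNodes))
  if (!length(seedNodes)) stop("seed set must be non-empty")
  if (!all(seedNodes %in% graph@nodes))
    stop("seed nodes must belong to the graph")
  if (any(schedule < 0)) stop("schedule entries must be >= 0")

  e <- graph@edges
  nbr <- c(split(data.frame(other = e$to, conf = e$confidence), e$from),
           split(data.frame(other = e$from, conf = e$confidence), e$to))
  nbr <- tapply(seq_along(nbr), names(nbr), function(ix)
    do.call(rbind, nbr[ix]), simplify = FALSE)
  degree <- stats::setNames(integer(length(graph@nodes)), graph@nodes)
  dtab <- table(c(e$from, e$to))
  degree[names(dtab)] <- as.integer(dtab)

  inSet <- stats::setNames(logical(length(graph@nodes)), graph@nodes)
  inSet[seedNodes] <- TRUE
  score <- stats::setNames(numeric(length(graph@nodes)), graph@nodes)
  for (v in seedNodes) {
    nb <- nbr[[v]]
    if (!is.null(nb)) {
      add <- tapply(nb$conf, nb$other, sum)
      score[names(add)] <- score[names(add)] + add
    }
  }
  nodeSets <- list(sort(seedNodes))
  saturated <- FALSE
  for (s in seq_along(schedule)) {
    for (j in seq_len(schedule[s])) {
      cand <- names(score)[!inSet & score > 0]
      if (!length(cand)) {
        saturated <- TRUE
        break
      }
      cand <- cand[order(-score[cand], -degree[cand], cand)]
      v <- cand[1]
      inSet[v] <- TRUE
      nb <- nbr[[v]]
      if (!is.null(nb)) {
        ext <- !inSet[nb$other]
        if (any(ext)) {
          add <- tapply(nb$conf[ext], nb$other[ext], sum)
          score[names(add)] <- score[names(add)] + add
        }
      }
    }
    nodeSets[[s + 1L]] <- sort(names(inSet)[inSet])
  }
  new("GrowthTrajectory", tfGroup = as.integer(tfGroup), nodeSets = nodeSets,
      saturated = saturated)
}

#' GO profile of a network node set
#'
#' Maps the nodes into the annotation universe (unmapped nodes are dropped
#' with a message), runs \code{\link{hypergeomEnrich}} and keeps terms below
#' the strict FDR cutoff.
#'
#' @param nodeSet character node ids
#' @param termMap named list term -> genes
#' @param universe annotation universe
#' @param fdrMax strict FDR cutoff (default 1e-4)
#' @return character vector of enriched term ids (possibly empty)
#' @export
networkGoProfile <- function(nodeSet, termMap, universe, fdrMax = 1e-4) {
  mapped <- intersect(unique(nodeSet), universe)
  dropped <- length(unique(nodeSet)) - length(mapped)
  if (dropped > 0)
    message(dropped, " node(s) not in the annotation universe were dropped")
  if (!length(mapped)) {
    warning("no node maps into the annotation universe")
    return(character(0))
  }
  rec <- hypergeomEnrich(mapped, termMap, universe)
  filterTerms(rec, fdrMax)$term
}

#' Sensitivity and specificity of a network's GO profile
#'
#' Sensitivity = percentage of DET-derived terms shared with the network's
#' terms; specificity = percentage of the network's terms shared with the
#' DET-derived ones (0 when the network has no terms).
#'
#' @param netTerms term ids enriched in the network
#' @param detTerms term ids enriched in the DET list (non-empty)
#' @return named numeric: \code{sensitivity}, \code{specificity} (percent)
#' @export
sensitivitySpecificity <- function(netTerms, detTerms) {
  detTerms <- unique(detTerms)
  netTerms <- unique(netTerms)
  if (!length(detTerms)) stop("detTerms must be non-empty")
  shared <- length(intersect(netTerms, detTerms))
  c(sensitivity = 100 * shared / length(detTerms),
    specificity = if (length(netTerms)) 100 * shared / length(netTerms) else 0)
}

#' Per-layer growth percentage of a trajectory
#'
#' growth(layer) = 100 (|nodes_layer| - |nodes_0|) / |nodes_0|.
#'
#' @param trajectory a \linkS4class{GrowthTrajectory}
#' @return numeric vector, one value per layer (layer 0 first)
#' @export
growthPercent <- function(trajectory) {
  sizes <- lengths(trajectory@nodeSets)
  100 * (sizes - sizes[1]) / sizes[1]
}

#' Attach GO / sensitivity / specificity / growth statistics per layer
#'
#' @param trajectory a \linkS4class{GrowthTrajectory}
#' @param termMap,universe,fdrMax passed to \code{\link{networkGoProfile}}
#' @param detTerms DET-derived enriched terms
#' @return the trajectory with its \code{stats} slot filled (columns group,
#'   layer, nNodes, nTerms, sensitivity, specificity, growth)
#' @export
profileTrajectory <- function(trajectory, termMap, universe, detTerms,
                              fdrMax = 1e-4) {
  gr <- growthPercent(trajectory)
  rows <- lapply(seq_along(trajectory@nodeSets), function(i) {
    terms <- suppressMessages(
      networkGoProfile(trajectory@nodeSets[[i]], termMap, universe, fdrMax))
    ss <- sensitivitySpecificity(terms, detTerms)
    data.frame(group = trajectory@tfGroup, layer = i - 1L,
               nNodes = length(trajectory@nodeSets[[i]]),
               nTerms = length(terms), sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]], growth = gr[i])
  })
  trajectory@stats <- do.call(rbind, rows)
  trajectory
}

#' Select the balanced TF-PPI network
#'
#' Candidates are the layers with sensitivity >= \code{sensMin} and growth
#' >= \code{growthMin}; the winner maximizes specificity, ties going to
#' fewer nodes and then the lower TF group index.  When no layer qualifies
#' the layer with maximal sensitivity is returned with
#' \code{relaxed = TRUE}.
#'
#' @param trajectories list of profiled \linkS4class{GrowthTrajectory}
#'   objects (stats filled)
#' @param sensMin sensitivity threshold in percent (default 40)
#' @param growthMin growth threshold in percent (default 150)
#' @return list with \code{tfGroup}, \code{layer}, \code{relaxed},
#'   \code{row} (the winning stats row) and \code{nodes} (the winning node
#'   set)
#' @export
selectNetwork <- function(trajectories, sensMin = 40, growthMin = 150) {
  if (!length(trajectories)) stop("need >= 1 trajectory")
  all <- do.call(rbind, lapply(trajectories, layerStats))
  if (is.null(all) || !nrow(all)) stop("trajectories must be profiled first")
  cand <- all[all$sensitivity >= sensMin & all$growth >= growthMin, ,
              drop = FALSE]
  relaxed <- !nrow(cand)
  if (relaxed) {
    ord <- order(-all$sensitivity, all$nNodes, all$group)
    win <- all[ord[1], ]
  } else {
    ord <- order(-cand$specificity, cand$nNodes, cand$group)
    win <- cand[ord[1], ]
  }
  traj <- trajectories[[which(vapply(trajectories, function(t)
    t@tfGroup, 0L) == win$group)[1]]]
  list(tfGroup = win$group, layer = win$layer, relaxed = relaxed, row = win,
       nodes = traj@nodeSets[[win$layer + 1L]])
}

#' Partition a network into core / secondary / peripheral tiers by k-means
#'
#' Per-node features: within-network degree, summed edge confidence and
#' closeness centrality (edge distances 1/confidence) on the induced
#' subgraph, standardized, then k-means with a fixed seed and 50 restarts.
#' Clusters are ranked by mean within-network degree; with k = 3 they are
#' labelled core, secondary and peripheral.
#'
#' @param nodeSet node ids of the selected network (length >= k)
#' @param graph the full \linkS4class{InteractionGraph}
#' @param k number of tiers (default 3)
#' @param seed RNG seed for k-means (default 1)
#' @return named character vector node -> tier label
#' @export
partitionNetworkKmeans <- function(nodeSet, graph, k = 3, seed = 1) {
  stopifnot(is(graph, "InteractionGraph"))
  nodeSet <- unique(nodeSet)
  if (k > length(nodeSet)) stop("k exceeds the number of nodes")
  e <- graph@edges
  keep <- e$from %in% nodeSet & e$to %in% nodeSet
  e <- e[keep, , drop = FALSE]
  deg <- strength <- stats::setNames(numeric(length(nodeSet)), nodeSet)
  dtab <- table(c(e$from, e$to))
  deg[names(dtab)] <- as.integer(dtab)
  for (i in seq_len(nrow(e))) {
    strength[e$from[i]] <- strength[e$from[i]] + e$confidence[i]
    strength[e$to[i]] <- strength[e$to[i]] + e$confidence[i]
  }
  sub <- igraph::graph_from_data_frame(
    e, directed = FALSE, vertices = data.frame(name = nodeSet))
  clo <- suppressWarnings(
    igraph::closeness(sub, weights = 1 / e$confidence, normalized = TRUE))
  clo[!is.finite(clo)] <- 0
  feats <- cbind(degree = deg, strength = strength,
                 closeness = clo[nodeSet])
  sdv <- apply(feats, 2, stats::sd)
  feats <- scale(feats[, sdv > 0, drop = FALSE])
  if (!ncol(feats)) feats <- cbind(degree = deg)  # fully regular network
  ## fewer distinct feature profiles than tiers (e.g. a pure star): cluster
  ## what is distinguishable and leave the higher tiers for the distinct rows
  kEff <- min(k, nrow(unique(feats)))
  set.seed(seed)
  km <- stats::kmeans(feats, centers = kEff, nstart = 50)
  rank <- order(-tapply(deg, km$cluster, mean))
  tierNames <- if (k == 3) c("core", "secondary", "peripheral")
               else paste0("tier", seq_len(k))
  lab <- stats::setNames(character(length(nodeSet)), nodeSet)
  for (i in seq_len(kEff)) lab[km$cluster == rank[i]] <- tierNames[i]
  lab
}
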