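#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
#' @importFrom BiocGenerics counts
NULL

## ---------------------------------------------------------------------------
## TimecourseExperiment: counts + per-sample time/surgeon/batch metadata
## ---------------------------------------------------------------------------

#' Time-course count container
#'
#' A \linkS4class{SummarizedExperiment} holding a transcripts x samples matrix
#' of raw counts (assay \code{"counts"}) together with the per-sample design
#' columns \code{time}, \code{surgeon} and \code{batch}.  \code{time} is an
#' ordered factor over the design's group labels (e.g. \code{"0min"},
#' \code{"45min"}, \code{"24h"}).
#'
#' @export
setClass("TimecourseExperiment", contains = "SummarizedExperiment")

setValidity("TimecourseExperiment", function(object) {
  msg <- character(0)
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (any(is.na(m)) || any(m < 0))
      msg <- c(msg, "counts must be non-negative and non-missing")
    if (any(abs(m - round(m)) > 1e-8))
      msg <- c(msg, "counts must be integers")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "transcript IDs (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample IDs (colnames) must be present and unique")
  if (!"time" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'time' column")
  if (length(msg)) msg else TRUE
})

#' Construct a TimecourseExperiment
#'
#' @param counts integer matrix, transcripts as rows (rownames = transcript
#'   IDs), samples as columns (colnames = sample IDs).
#' @param sampleData data.frame with one row per sample and at least a
#'   \code{time} column; \code{surgeon} and \code{batch} columns are carried
#'   along when present.
#' @param timeLevels optional ordering of the time labels; defaults to order
#'   of first appearance.
#' @return a \linkS4class{TimecourseExperiment}
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 2,
#'             dimnames = list(c("T1", "T2"), paste0("S", 1:6)))
#' tce <- TimecourseExperiment(m, data.frame(time = rep(c("0min", "24h"), 3)))
#' @export
TimecourseExperiment <- function(counts, sampleData,
                                 timeLevels = unique(as.character(sampleData$time))) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("T%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  sampleData <- as.data.frame(sampleData)
  if (nrow(sampleData) != ncol(counts))
    stop("sampleData must have one row per sample")
  sampleData$time <- factor(as.character(sampleData$time), levels = timeLevels)
  if (any(is.na(sampleData$time)))
    stop("every sample needs a time label drawn from 'timeLevels'")
  rownames(sampleData) <- colnames(counts)
  new("TimecourseExperiment",
      SummarizedExperiment(assays = list(counts = counts),
                           colData = S4Vectors::DataFrame(sampleData)))
}

#' @describeIn TimecourseExperiment raw count matrix accessor
#' @param object,x a TimecourseExperiment
#' @export
setMethod("counts", "TimecourseExperiment", function(object) {
  assay(object, "counts")
})

#' Time labels of a TimecourseExperiment
#' @param x a TimecourseExperiment
#' @return factor of per-sample time labels
#' @export
timeLabels <- function(x) colData(x)$time

## ---------------------------------------------------------------------------
## ModulePartition
## ---------------------------------------------------------------------------

#' Co-expression module partition
#'
#' Maps every clustered transcript to a module index; index 0 is the
#' "unassigned" (grey) class.  Non-zero modules are numbered by decreasing
#' size.
#'
#' @slot labels named integer vector, transcript -> module index (0 =
#'   unassigned)
#' @export
setClass("ModulePartition", representation(labels = "integer"))

setValidity("ModulePartition", function(object) {
  msg <- character(0)
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
    msg <- c(msg, "labels must be uniquely named by transcript")
  if (any(object@labels < 0)) msg <- c(msg, "module indices must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ModulePartition-class
#' @param labels named integer vector of module indices (0 = unassigned)
#' @export
ModulePartition <- function(labels) {
  lab <- as.integer(labels)
  names(lab) <- names(labels)
  new("ModulePartition", labels = lab)
}

#' @rdname ModulePartition-class
#' @param x a ModulePartition
#' @export
moduleLabels <- function(x) x@labels

#' @rdname ModulePartition-class
#' @export
moduleSizes <- function(x) {
  lab <- x@labels[x@labels > 0L]
  if (!length(lab)) return(integer(0))
  tab <- table(lab)
  stats::setNames(as.integer(tab), names(tab))
}

#' @rdname ModulePartition-class
#' @param module module index
#' @export
moduleMembers <- function(x, module) {
  names(x@labels)[x@labels == module]
}

#' Percentage of transcripts left unassigned by module detection
#' @param x a ModulePartition
#' @return percentage in [0, 100]
#' @export
unassignedPercent <- function(x) {
  100 * sum(x@labels == 0L) / length(x@labels)
}

setMethod("show", "ModulePartition", function(object) {
  sz <- moduleSizes(object)
  cat("ModulePartition:", length(object@labels), "transcripts,",
      length(sz), "modules\n")
  if (length(sz))
    cat("  module sizes:", paste(sz, collapse = ", "), "\n")
  cat(sprintf("  unassigned: %d (%.1f%%)\n",
              sum(object@labels == 0L), unassignedPercent(object)))
})

## ---------------------------------------------------------------------------
## Simulation design
## ---------------------------------------------------------------------------

#' Planted co-expression module description
#'
#' @slot name module label
#' @slot size number of transcripts (>= 3)
#' @slot profile one of \code{"transient_45min"} (effect on the middle time
#'   group only), \code{"up_24h"} (positive effect on the last group),
#'   \code{"down_24h"} (negative effect on the last group) or \code{"null"}
#'   (co-expressed but not differential).
#' @slot log2Effect magnitude of the log2 fold change applied on the
#'   profile's active group(s); \code{down_24h} applies it with negative sign
#' @slot withinCorrelation weight in [0,1] of the shared per-sample latent
#'   factor inducing within-module correlation
#' @export
setClass("PlantedModule",
         representation(name = "character", size = "integer",
                        profile = "character", log2Effect = "numeric",
                        withinCorrelation = "numeric"))

setValidity("PlantedModule", function(object) {
  msg <- character(0)
  if (object@size < 3L) msg <- c(msg, "module size must be >= 3")
  if (!object@profile %in% c("transient_45min", "up_24h", "down_24h", "null"))
    msg <- c(msg, "unknown profile")
  if (object@profile == "null" && object@log2Effect != 0)
    msg <- c(msg, "null profile requires log2Effect = 0")
  if (object@withinCorrelation < 0 || object@withinCorrelation > 1)
    msg <- c(msg, "withinCorrelation must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @rdname PlantedModule-class
#' @param name,size,profile,log2Effect,withinCorrelation see slots
#' @export
plantedModule <- function(name, size, profile,
                          log2Effect = if (profile == "null") 0 else 2,
                          withinCorrelation = 0.3) {
  new("PlantedModule", name = name, size = as.integer(size), profile = profile,
      log2Effect = log2Effect, withinCorrelation = withinCorrelation)
}

#' Simulation design for the synthetic surgical time course
#'
#' @slot nTranscripts total number of transcripts
#' @slot groups ordered time labels
#' @slot nPerGroup replicates per time point (>= 2)
#' @slot baselineMean expected baseline count
#' @slot dispersion NB dispersion alpha (Var = mu + alpha mu^2)
#' @slot modules list of \linkS4class{PlantedModule}
#' @slot batchLog2Effect optional log2 batch effect (0 = none)
#' @slot seed RNG seed
#' @export
setClass("SimulationDesign",
         representation(nTranscripts = "integer", groups = "character",
                        nPerGroup = "integer", baselineMean = "numeric",
                        dispersion = "numeric", modules = "list",
                        batchLog2Effect = "numeric", seed = "integer"))

setValidity("SimulationDesign", function(object) {
  msg <- character(0)
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be >= 2")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (object@baselineMean <= 0) msg <- c(msg, "baselineMean must be > 0")
  if (length(object@groups) < 2L) msg <- c(msg, "need >= 2 time groups")
  if (!all(vapply(object@modules, is, TRUE, "PlantedModule")))
    msg <- c(msg, "modules must be PlantedModule objects")
  nm <- vapply(object@modules, function(m) m@name, "")
  if (anyDuplicated(nm)) msg <- c(msg, "module names must be unique")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationDesign-class
#' @param nTranscripts,groups,nPerGroup,baselineMean,dispersion,modules,batchLog2Effect,seed
#'   see slots
#' @export
simulationDesign <- function(nTranscripts = 2000,
                             groups = c("0min", "45min", "24h"),
                             nPerGroup = 8, baselineMean = 100,
                             dispersion = 0.05, modules = list(),
                             batchLog2Effect = 0, seed = 1) {
  new("SimulationDesign", nTranscripts = as.integer(nTranscripts),
      groups = groups, nPerGroup = as.integer(nPerGroup),
      baselineMean = baselineMean, dispersion = dispersion, modules = modules,
      batchLog2Effect = batchLog2Effect, seed = as.integer(seed))
}

#' Default simulation design of the synthetic surgical study
#'
#' Three time points (0 min, 45 min, 24 h) with 8 replicates each, 2000
#' transcripts, and three planted temporal modules: a transient 45-min
#' induction, a 24-h up-regulated and a 24-h down-regulated module.
#'
#' @param seed RNG seed
#' @param nTranscripts total transcript count (default 2000)
#' @return a \linkS4class{SimulationDesign}
#' @export
defaultSimulationDesign <- function(seed = 1, nTranscripts = 2000) {
  simulationDesign(
    nTranscripts = nTranscripts,
    modules = list(
      plantedModule("transient45", 60, "transient_45min"),
      plantedModule("up24h", 80, "up_24h"),
      plantedModule("down24h", 70, "down_24h")),
    seed = seed)
}

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Planted ground truth of a synthetic study
#'
#' Filled incrementally: \code{\link{simulateCounts}} sets module labels and
#' the true differential set; \code{\link{simulateAnnotations}} adds the GO
#' term and category maps; \code{\link{simulateTfAndPpi}} adds TF target
#' sets, the upstream hub and its signalling cascade.
#'
#' @slot moduleLabels named character, transcript -> module name or
#'   "unassigned"
#' @slot deTranscripts truly non-null transcripts (union of non-null modules)
#' @slot termMap named list, GO term -> gene set
#' @slot categoryMap named character, GO term -> process category
#' @slot tfTargets named list, TF -> target gene set
#' @slot drivenTfs TFs whose targets were planted in the differential set
#' @slot hubNode planted upstream regulator node
#' @slot cascade ordered node path from hub towards the driven TFs
#' @export
setClass("GroundTruth",
         representation(moduleLabels = "character", deTranscripts = "character",
                        termMap = "list", categoryMap = "character",
                        tfTargets = "list", drivenTfs = "character",
                        hubNode = "character", cascade = "character"),
         prototype(termMap = list(), categoryMap = character(0),
                   tfTargets = list(), drivenTfs = character(0),
                   hubNode = character(0), cascade = character(0)))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@moduleLabels), "transcripts,",
      length(object@deTranscripts), "planted DE,",
      length(object@termMap), "terms,", length(object@tfTargets), "TFs\n")
  if (length(object@hubNode)) cat("  hub:", object@hubNode, "\n")
})

#' @rdname GroundTruth-class
#' @param x a GroundTruth
#' @export
trueModuleLabels <- function(x) x@moduleLabels

#' @rdname GroundTruth-class
#' @export
trueDeTranscripts <- function(x) x@deTranscripts

#' @rdname GroundTruth-class
#' @export
trueHubNode <- function(x) x@hubNode

## ---------------------------------------------------------------------------
## InteractionGraph
## ---------------------------------------------------------------------------

#' Weighted protein-protein interaction graph
#'
#' Undirected simple graph with per-edge confidence in (0, 1].
#'
#' @slot nodes character node ids
#' @slot edges data.frame(from, to, confidence)
#' @export
setClass("InteractionGraph",
         representation(nodes = "character", edges = "data.frame"))

setValidity("InteractionGraph", function(object) {
  msg <- character(0)
  e <- object@edges
  if (!all(c("from", "to", "confidence") %in% colnames(e)))
    msg <- c(msg, "edges need columns from, to, confidence")
  else {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$confidence <= 0 | e$confidence > 1))
      msg <- c(msg, "confidences must be in (0, 1]")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be listed in nodes")
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
  if (length(msg)) msg else TRUE
})

#' @rdname InteractionGraph-class
#' @param edges data.frame with columns from, to, confidence
#' @param nodes optional node ids (to include isolated nodes)
#' @export
InteractionGraph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  colnames(edges)[1:3] <- c("from", "to", "confidence")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  nodes <- sort(unique(c(edges$from, edges$to, as.character(nodes))))
  new("InteractionGraph", nodes = nodes, edges = edges)
}

#' @rdname InteractionGraph-class
#' @param x an InteractionGraph
#' @export
graphNodes <- function(x) x@nodes

#' @rdname InteractionGraph-class
#' @export
graphEdges <- function(x) x@edges

setMethod("show", "InteractionGraph", function(object) {
  cat("InteractionGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
})

## internal: igraph view (weights = confidence)
.asIgraph <- function(x) {
  igraph::graph_from_data_frame(
    x@edges, directed = FALSE,
    vertices = data.frame(name = x@nodes, stringsAsFactors = FALSE))
}

## ---------------------------------------------------------------------------
## GrowthTrajectory
## ---------------------------------------------------------------------------

#' Layered growth of a TF-seeded PPI subnetwork
#'
#' Layer 0 is the seed ("initial") network; each later layer adds the
#' scheduled number of highest-confidence external neighbours.
#'
#' @slot tfGroup TF group index the seeds came from (NA when free-standing)
#' @slot nodeSets list of per-layer node id vectors (layer 0 first)
#' @slot saturated TRUE when expansion ran out of external neighbours
#' @slot stats per-layer statistics filled by \code{\link{profileTrajectory}}
#' @export
setClass("GrowthTrajectory",
         representation(tfGroup = "integer", nodeSets = "list",
                        saturated = "logical", stats = "data.frame"),
         prototype(tfGroup = NA_integer_, saturated = FALSE,
                   stats = data.frame()))

setValidity("GrowthTrajectory", function(object) {
  msg <- character(0)
  ns <- object@nodeSets
  if (!length(ns)) msg <- c(msg, "at least the seed layer is required")
  for (i in seq_along(ns)[-1])
    if (!all(ns[[i - 1]] %in% ns[[i]]))
      msg <- c(msg, "node sets must be nested across layers")
  if (length(msg)) msg else TRUE
})

#' @rdname GrowthTrajectory-class
#' @param x a GrowthTrajectory
#' @export
layerNodeSets <- function(x) x@nodeSets

#' @rdname GrowthTrajectory-class
#' @export
layerStats <- function(x) x@stats

setMethod("show", "GrowthTrajectory", function(object) {
  cat("GrowthTrajectory (TF group", object@tfGroup, "):",
      length(object@nodeSets) - 1L, "growth layers, sizes",
      paste(lengths(object@nodeSets), collapse = " -> "),
      if (object@saturated) "(saturated)" else "", "\n")
})
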