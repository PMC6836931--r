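#' Hypergeometric gene-set enrichment with BH correction
#'
#' Per term, p = P(X >= x) for X hypergeometric with population size
#' |universe|, |term in universe| successes and |geneSet| draws.  Terms with
#' zero overlap are excluded from testing; BH runs across the tested terms.
#'
#' @param geneSet character vector of gene ids (must be a subset of
#'   \code{universe})
#' @param termMap named list, term -> gene ids
#' @param universe character vector of background gene ids
#' @return data.frame(term, x, termSize, setSize, universeSize, pvalue, fdr)
#'   sorted as in \code{termMap}
#' @examples
#' hypergeomEnrich(paste0("g", 1:4),
#'                 list(T1 = paste0("g", 1:5)), paste0("g", 1:10))
#' @export
hypergeomEnrich <- function(geneSet, termMap, universe) {
  geneSet <- unique(geneSet)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!length(geneSet)) stop("empty gene set")
  if (!all(geneSet %in% universe))
    stop("gene set must be a subset of the universe")
  n <- length(geneSet)
  N <- length(universe)
  K <- vapply(termMap, function(g) length(intersect(g, universe)), 0L)
  x <- vapply(termMap, function(g) length(intersect(g, geneSet)), 0L)
  keep <- x > 0L
  res <- data.frame(term = names(termMap)[keep], x = x[keep],
                    termSize = K[keep], setSize = n, universeSize = N,
                    stringsAsFactors = FALSE)
  res$pvalue <- stats::phyper(res$x - 1L, res$termSize, N - res$termSize, n,
                              lower.tail = FALSE)
  res$fdr <- bhAdjust(res$pvalue)
  rownames(res) <- NULL
  res
}

#' Keep terms below a strict FDR cutoff
#'
#' Strict inequality (\code{fdr < fdrMax}); input order preserved.
#'
#' @param records data.frame carrying an \code{fdr} column
#' @param fdrMax cutoff (default 1e-4)
#' @return filtered data.frame
#' @export
filterTerms <- function(records, fdrMax = 1e-4) {
  stopifnot("fdr" %in% colnames(records))
  records[records$fdr < fdrMax, , drop = FALSE]
}

#' Continuity-corrected module-versus-DET enrichment z-score
#'
#' z = (x - 0.5 - B n / N) / sqrt(vf * n * (B/N) * (1 - B/N)) where x is the
#' count of module-group transcripts in the term, B the count of DETs in the
#' term, n the module-group size and N the DET count.  The variance factor
#' \code{vf} defaults to 1 (standard continuity-corrected binomial z); set
#' \code{eq1VarianceFactor = 2} for the doubled-variance reading.
#'
#' @param x,B,n,N see description (vectorized over \code{x} and \code{B})
#' @param eq1VarianceFactor multiplier on the variance term (default 1)
#' @return numeric z-score(s)
#' @examples
#' moduleTermZscore(20, 100, 100, 1000)  # (20 - 0.5 - 10) / 3 = 3.1667
#' @export
moduleTermZscore <- function(x, B, n, N, eq1VarianceFactor = 1) {
  if (any(B <= 0) || any(B >= N))
    stop("z-score undefined for B = 0 or B = N")
  p <- B / N
  (x - 0.5 - n * p) / sqrt(eq1VarianceFactor * n * p * (1 - p))
}

#' Enumerate all non-empty combinations of selected modules
#'
#' @param moduleGenes named list, module id -> transcript ids (1 to 6
#'   modules)
#' @return named list of 2^k - 1 transcript sets; names are canonical
#'   \code{"[i;j;...]"} with ascending module ids
#' @export
enumerateModuleGroups <- function(moduleGenes) {
  ids <- names(moduleGenes)
  if (is.null(ids) || anyDuplicated(ids)) stop("duplicate or missing module ids")
  k <- length(ids)
  if (k < 1 || k > 6) stop("between 1 and 6 modules are supported")
  ord <- order(suppressWarnings(as.numeric(ids)), ids, na.last = TRUE)
  ids <- ids[ord]
  out <- list()
  for (m in 1:k) {
    for (sel in utils::combn(ids, m, simplify = FALSE)) {
      nm <- paste0("[", paste(sel, collapse = ";"), "]")
      out[[nm]] <- sort(unique(unlist(moduleGenes[sel])))
    }
  }
  out
}

#' Enrich every module group against the DET universe with the z-score
#'
#' Runs \code{\link{hypergeomEnrich}} for each group with the DET list as
#' universe, attaches B (term count among DETs) and the continuity-corrected
#' z, and flags records enriched when \code{fdr < fdrMax} and
#' \code{z > zMin}.
#'
#' @param groups named list, group name -> transcript set (e.g. from
#'   \code{\link{enumerateModuleGroups}})
#' @param detGenes DET transcript ids (the universe, N)
#' @param termMap named list term -> genes
#' @param fdrMax strict FDR cutoff (default 1e-4)
#' @param zMin enrichment z cutoff (default 2)
#' @param eq1VarianceFactor see \code{\link{moduleTermZscore}}
#' @return data.frame(group, groupSize, term, x, B, n, N, pvalue, fdr, z,
#'   enriched)
#' @export
moduleGroupEnrichment <- function(groups, detGenes, termMap, fdrMax = 1e-4,
                                  zMin = 2, eq1VarianceFactor = 1) {
  detGenes <- unique(detGenes)
  N <- length(detGenes)
  Bv <- vapply(termMap, function(g) length(intersect(g, detGenes)), 0L)
  out <- list()
  for (gn in names(groups)) {
    gg <- intersect(groups[[gn]], detGenes)
    if (!length(gg)) next
    he <- hypergeomEnrich(gg, termMap, detGenes)
    if (!nrow(he)) next
    B <- Bv[he$term]
    ok <- B > 0 & B < N
    he <- he[ok, , drop = FALSE]
    B <- B[ok]
    z <- moduleTermZscore(he$x, B, length(gg), N, eq1VarianceFactor)
    out[[gn]] <- data.frame(group = gn, groupSize = length(gg),
                            term = he$term, x = he$x, B = as.integer(B),
                            n = length(gg), N = N, pvalue = he$pvalue,
                            fdr = he$fdr, z = z,
                            enriched = he$fdr < fdrMax & z > zMin,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(group = character(0), groupSize = integer(0),
                      term = character(0), x = integer(0), B = integer(0),
                      n = integer(0), N = integer(0), pvalue = numeric(0),
                      fdr = numeric(0), z = numeric(0), enriched = logical(0))
  rownames(res) <- NULL
  res
}

#' Assign each enriched term to its best-predicting module group
#'
#' Among the enriched records (already filtered on FDR and z), every term is
#' counted exactly once in the group with the highest z; ties go to the
#' smaller group, then to the lexicographically smaller group name.
#'
#' @param records data.frame from \code{\link{moduleGroupEnrichment}} rows
#'   with \code{enriched == TRUE} (columns group, groupSize, term, z)
#' @return list with \code{assignment} (named character, term -> group) and
#'   \code{counts} (named integer per group)
#' @export
bestPredictorAssignment <- function(records) {
  if (!nrow(records))
    return(list(assignment = character(0), counts = integer(0)))
  ord <- order(records$term, -records$z, records$groupSize, records$group)
  r <- records[ord, ]
  first <- !duplicated(r$term)
  assignment <- stats::setNames(r$group[first], r$term[first])
  tab <- table(assignment)
  list(assignment = assignment,
       counts = stats::setNames(as.integer(tab), names(tab)))
}

#' Roll enriched terms up into process categories
#'
#' @param terms character vector of term ids
#' @param categoryMap named character, term -> category
#' @return list with \code{table} (data.frame category, count, percentage;
#'   percentages over classified terms sum to 100) and \code{unassigned}
#'   (terms missing from the map)
#' @export
rollupProcesses <- function(terms, categoryMap) {
  terms <- unique(terms)
  known <- terms[terms %in% names(categoryMap)]
  unassigned <- setdiff(terms, known)
  if (!length(known))
    return(list(table = data.frame(category = character(0), count = integer(0),
                                   percentage = numeric(0)),
                unassigned = unassigned))
  tab <- sort(table(categoryMap[known]), decreasing = TRUE)
  list(table = data.frame(category = names(tab), count = as.integer(tab),
                          percentage = 100 * as.integer(tab) / length(known),
                          stringsAsFactors = FALSE),
       unassigned = unassigned)
}
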