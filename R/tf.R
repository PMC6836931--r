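#' TF target-set over-representation among DETs
#'
#' Per TF, a 2x2 table (target set vs background x TF-target yes/no) is
#' scored with a one-tailed (enrichment) Fisher exact test; the F-score is
#' -ln of that p-value.  A continuity-corrected normal approximation to the
#' binomial gives z = (hits_target - 0.5 - n_target p0) /
#' sqrt(n_target p0 (1 - p0) vf) with the background rate
#' p0 = hits_bg / n_bg.  Records with p0 in {0, 1} have no defined z and are
#' flagged for exclusion from grouping.
#'
#' @param targetSet gene ids of the foreground (e.g. the DET list)
#' @param backgroundSet gene ids of the background (disjoint from the
#'   foreground)
#' @param tfTargets named list, TF -> target gene ids
#' @param varianceFactor multiplier on the z variance term (default 1)
#' @return data.frame(tf, hitsTarget, nTarget, hitsBg, nBg, fisherP, fScore,
#'   zScore, zDefined)
#' @export
tfOverrepresentation <- function(targetSet, backgroundSet, tfTargets,
                                 varianceFactor = 1) {
  targetSet <- unique(targetSet)
  backgroundSet <- unique(backgroundSet)
  if (!length(targetSet) || !length(backgroundSet))
    stop("target and background sets must be non-empty")
  if (length(intersect(targetSet, backgroundSet)))
    stop("target and background sets must be disjoint")
  nT <- length(targetSet)
  nB <- length(backgroundSet)
  res <- lapply(names(tfTargets), function(tf) {
    tg <- tfTargets[[tf]]
    hT <- length(intersect(tg, targetSet))
    hB <- length(intersect(tg, backgroundSet))
    p <- stats::fisher.test(matrix(c(hT, nT - hT, hB, nB - hB), 2),
                            alternative = "greater")$p.value
    p0 <- hB / nB
    zDef <- p0 > 0 && p0 < 1
    z <- if (zDef)
      (hT - 0.5 - nT * p0) / sqrt(nT * p0 * (1 - p0) * varianceFactor)
    else NA_real_
    data.frame(tf = tf, hitsTarget = hT, nTarget = nT, hitsBg = hB, nBg = nB,
               fisherP = p, fScore = -log(p), zScore = z, zDefined = zDef,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Filter TFs by F-score and form the five nested z-score groups
#'
#' TFs with \code{fScore > fMin} (strict) and a defined z are kept; group g
#' collects the kept TFs with |z| above the g-th cut.  With strictly
#' decreasing cuts the groups are nested: group 1 is the most stringent and
#' every member of group g also belongs to group g + 1.
#'
#' @param records data.frame from \code{\link{tfOverrepresentation}}
#' @param fMin F-score cutoff (default 20, i.e. p < exp(-20))
#' @param zCuts strictly decreasing |z| cuts (default 35, 25, 15, 10, 2)
#' @return list with \code{records} (kept rows plus logical group columns)
#'   and \code{groups} (list of TF id vectors, one per cut)
#' @export
filterAndGroupTfs <- function(records, fMin = 20, zCuts = c(35, 25, 15, 10, 2)) {
  if (any(diff(zCuts) >= 0)) stop("zCuts must be strictly decreasing")
  keep <- records$fScore > fMin & records$zDefined
  r <- records[keep, , drop = FALSE]
  groups <- vector("list", length(zCuts))
  names(groups) <- paste0("group", seq_along(zCuts))
  for (g in seq_along(zCuts)) {
    member <- abs(r$zScore) > zCuts[g]
    r[[names(groups)[g]]] <- member
    groups[[g]] <- r$tf[member]
  }
  list(records = r, groups = groups)
}

#' Invert the F-score back to its Fisher p-value
#'
#' \code{exp(-fScore)}; e.g. an F-score cutoff of 20 corresponds to
#' p = 2.06e-9.
#'
#' @param fScore numeric F-score(s)
#' @return p-value(s)
#' @export
fScoreToPvalue <- function(fScore) exp(-fScore)
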