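## Signed weighted co-expression: soft-thresholded correlation -> topological
## overlap -> average-linkage clustering -> static cut + minimum-size merge.

#' Pick the soft threshold by the scale-free topology criterion
#'
#' For each candidate exponent beta the signed adjacency is built, the
#' connectivity distribution p(k) is binned, and log10 p(k) is regressed on
#' log10 k.  The fit statistic is the signed index -sign(slope) R-squared,
#' so only negative-slope (power-law-like) fits can qualify.  The smallest
#' candidate reaching \code{fitTarget} wins; when none qualifies
#' \code{warningFlag} is set and the candidate with the best signed fit is
#' returned -- or, when no candidate shows a negative slope at all (as on
#' small module-dominated networks), the largest candidate, i.e. the
#' strongest thresholding on the grid.
#'
#' @param expr transcripts x samples expression matrix (typically restricted
#'   to the DETs)
#' @param candidates integer candidate exponents (default 1:30)
#' @param fitTarget minimum scale-free fit R-squared (default 0.8)
#' @param nBins connectivity histogram bins (default 10)
#' @return list with \code{beta}, \code{fitTable} (candidate, fit, slope) and
#'   \code{warningFlag}
#' @export
pickSoftThreshold <- function(expr, candidates = 1:30, fitTarget = 0.8,
                              nBins = 10) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 20) stop("need >= 20 transcripts")
  cc <- .safeCor(expr)
  fits <- slopes <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    a <- ((1 + cc) / 2)^candidates[i]
    diag(a) <- 0
    k <- rowSums(a)
    br <- seq(min(k), max(k), length.out = nBins + 1)
    bin <- cut(k, breaks = br, include.lowest = TRUE)
    pk <- tapply(k, bin, length) / length(k)
    km <- tapply(k, bin, mean)
    keep <- !is.na(pk) & pk > 0 & km > 0
    if (sum(keep) < 4)
      stop("fewer than 4 distinct connectivity bins at beta = ",
           candidates[i])
    fit <- stats::lm(log10(pk[keep]) ~ log10(km[keep]))
    r2 <- summary(fit)$r.squared
    slopes[i] <- stats::coef(fit)[2]
    fits[i] <- -sign(slopes[i]) * r2
  }
  hit <- which(fits >= fitTarget)
  if (length(hit)) {
    beta <- candidates[hit[1]]
    warn <- FALSE
  } else {
    warn <- TRUE
    beta <- if (all(slopes >= 0)) max(candidates)
            else candidates[which.max(fits)]
  }
  list(beta = beta,
       fitTable = data.frame(candidate = candidates, fit = fits,
                             slope = slopes),
       warningFlag = warn)
}

## correlation with zero-variance rows forced to 0 (logged)
.safeCor <- function(expr) {
  sdv <- apply(expr, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(expr)))
  if (any(sdv == 0)) {
    message(sum(sdv == 0), " constant transcript(s): correlations set to 0")
    cc[sdv == 0, ] <- 0
    cc[, sdv == 0] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Signed adjacency and topological overlap matrix
#'
#' Signed adjacency a_ij = ((1 + cor_ij) / 2)^beta (a_ii = 1); topological
#' overlap TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)
#' with k_i the off-diagonal row sum and the numerator sum running over
#' u != i, j.  Symmetric with entries in [0, 1] and unit diagonal.
#'
#' @param expr transcripts x samples expression matrix
#' @param beta soft-threshold exponent (>= 1)
#' @return TOM similarity matrix
#' @export
adjacencyTom <- function(expr, beta) {
  if (beta < 1) stop("beta must be >= 1")
  expr <- as.matrix(expr)
  a <- ((1 + .safeCor(expr)) / 2)^beta
  diag(a) <- 1
  k <- rowSums(a) - 1
  l <- a %*% a - 2 * a            # removes u = i and u = j terms (a_ii = 1)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- list(rownames(expr), rownames(expr))
  tom
}

#' Detect modules by average-linkage clustering of the TOM dissimilarity
#'
#' Hierarchical clustering on 1 - TOM, static cut at \code{cutHeight};
#' clusters smaller than \code{minModuleSize} are merged into the unassigned
#' class (label 0) and the remaining modules are renumbered by decreasing
#' size.  This static cut plus minimum-size merge approximates a dynamic
#' tree cut.
#'
#' @param tom TOM similarity matrix from \code{\link{adjacencyTom}}
#' @param minModuleSize smallest retained module (>= 3; default 20)
#' @param cutHeight tree cut height on the 1 - TOM scale (default 0.99)
#' @return a \linkS4class{ModulePartition}
#' @export
detectModules <- function(tom, minModuleSize = 20, cutHeight = 0.99) {
  if (minModuleSize < 3) stop("minModuleSize must be >= 3")
  stopifnot(isSymmetric(unname(tom)), all(tom >= -1e-8 & tom <= 1 + 1e-8))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cutHeight)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= minModuleSize])
  lab <- integer(length(cl))
  if (length(keep)) {
    ## renumber by decreasing size; ties by first appearance for determinism
    ord <- keep[order(-sizes[as.character(keep)],
                      match(keep, unique(cl)))]
    for (i in seq_along(ord)) lab[cl == ord[i]] <- i
  }
  names(lab) <- rownames(tom)
  ModulePartition(lab)
}

#' Module eigengenes and temporal profiles
#'
#' The eigengene of a module is the first principal component (unit-norm
#' right singular vector over samples) of the module's row-standardized
#' expression, sign-fixed so its correlation with the module's mean
#' standardized profile is non-negative.  Per-group eigengene means are
#' returned for profile plots.
#'
#' @param expr transcripts x samples expression matrix
#' @param partition a \linkS4class{ModulePartition}
#' @param time optional factor of per-sample time labels (for group means)
#' @return list with \code{eigengenes} (modules x samples),
#'   \code{varianceExplained} (per module), \code{groupMeans} (modules x
#'   groups, NULL without \code{time}) and \code{singular} (flags for
#'   degenerate all-constant modules)
#' @export
moduleEigengenes <- function(expr, partition, time = NULL) {
  expr <- as.matrix(expr)
  sz <- moduleSizes(partition)
  mods <- as.integer(names(sz))
  if (any(sz < 2)) stop("every module needs >= 2 transcripts")
  eg <- matrix(0, length(mods), ncol(expr),
               dimnames = list(paste0("M", mods), colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), rownames(eg))
  singular <- stats::setNames(logical(length(mods)), rownames(eg))
  for (i in seq_along(mods)) {
    sub <- expr[moduleMembers(partition, mods[i]), , drop = FALSE]
    sdv <- apply(sub, 1, stats::sd)
    if (all(sdv == 0)) {
      singular[i] <- TRUE
      next
    }
    sub <- sub[sdv > 0, , drop = FALSE]
    z <- t(scale(t(sub)))
    sv <- svd(z)
    v <- sv$v[, 1]
    if (stats::cor(v, colMeans(z)) < 0) v <- -v
    eg[i, ] <- v
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  gm <- NULL
  if (!is.null(time)) {
    time <- factor(time)
    gm <- t(apply(eg, 1, function(v) tapply(v, time, mean)))
    colnames(gm) <- levels(time)
  }
  list(eigengenes = eg, varianceExplained = ve, groupMeans = gm,
       singular = singular)
}
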