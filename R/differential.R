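#' Median-of-ratios size factors
#'
#' For each sample j, sf_j is the median over transcripts (positive in every
#' sample) of count_gj / geometric-mean_g; the vector is rescaled so its
#' geometric mean is 1.  This is the standard sequencing-depth offset used
#' by NB count models.
#'
#' @param x a \linkS4class{TimecourseExperiment} or a count matrix
#' @return named numeric vector of positive per-sample size factors
#' @examples
#' m <- matrix(c(2, 4, 3, 6, 10, 20), nrow = 3, byrow = TRUE)
#' medianRatioSizeFactors(m)
#' @export
medianRatioSizeFactors <- function(x) {
  m <- if (is(x, "TimecourseExperiment")) counts(x) else as.matrix(x)
  ok <- rowSums(m > 0) == ncol(m)
  if (!any(ok))
    stop("no transcript has positive counts in every sample; ",
         "a pseudo-reference fallback would be required")
  lg <- log(m[ok, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(m))
}

## ---------------------------------------------------------------------------
## NB likelihood machinery (log link, size-factor offsets)
## ---------------------------------------------------------------------------

## maximized log-likelihood of a single NB mean q (mu_j = q * sf_j) for
## fixed dispersion alpha; Newton on eta = log q (concave)
.nbFitGroup <- function(y, sf, alpha) {
  r <- 1 / alpha
  tot <- sum(y)
  if (tot == 0)
    return(list(q = 0, ll = 0))          # dnbinom(0, mu -> 0) -> 1
  eta <- log(tot / sum(sf))
  for (it in 1:50) {
    mu <- exp(eta) * sf
    grad <- tot - sum((y + r) * mu / (mu + r))
    hess <- -sum((y + r) * mu * r / (mu + r)^2)
    step <- grad / (-hess)
    step <- max(min(step, 5), -5)
    eta <- eta + step
    if (abs(step) < 1e-10) break
  }
  q <- exp(eta)
  list(q = q, ll = sum(stats::dnbinom(y, size = r, mu = q * sf, log = TRUE)))
}

## Cox-Reid adjusted profile log-likelihood of the grouped-means model at
## dispersion alpha; the adjustment -0.5 log det(X'WX) (which factorizes per
## group for a group-means design, w = mu / (1 + alpha mu)) removes the
## downward bias of plug-in ML dispersion at small group counts
.nbProfileLL <- function(y, sf, groupIdx, alpha) {
  sum(vapply(groupIdx, function(ix) {
    fit <- .nbFitGroup(y[ix], sf[ix], alpha)
    mu <- fit$q * sf[ix]
    w <- sum(mu / (1 + alpha * mu))
    fit$ll - 0.5 * log(max(w, 1e-12))
  }, 0))
}

## method-of-moments dispersion on normalized counts (fallback / init)
.momDispersion <- function(y, sf) {
  z <- y / sf
  m <- mean(z)
  v <- stats::var(z)
  if (!is.finite(v) || m <= 0) return(1e-8)
  max((v - m) / m^2, 1e-8)
}

#' Negative-binomial likelihood-ratio test across time groups
#'
#' Per transcript, fits an NB GLM with log link and size-factor offsets:
#' full model = one mean per time group, reduced model = one shared mean.
#' The per-transcript dispersion is estimated by maximum (profile)
#' likelihood under the full model, floored at 1e-8, and shared between the
#' two fits.  The LRT statistic 2(ll_full - ll_reduced) is by default
#' calibrated as a quasi-likelihood F test -- stat / (groups - 1) referred
#' to F(groups - 1, samples - groups) -- which accounts for the uncertainty
#' of the per-transcript dispersion estimate at small replicate numbers;
#' \code{calibration = "chisq"} gives the asymptotic chi-square reference
#' with (groups - 1) degrees of freedom.  P-values are BH
#' corrected over the tested transcripts.  All-zero transcripts are excluded
#' before testing.  This is a deliberately simplified NB-LRT (no dispersion
#' shrinkage across transcripts, no outlier handling, no independent
#' filtering), sufficient to produce the DET list the downstream stages
#' consume.
#'
#' @param x a \linkS4class{TimecourseExperiment}
#' @param sizeFactors per-sample size factors (default: median-of-ratios)
#' @param detFdr BH-FDR threshold flagging differentially expressed
#'   transcripts (default 0.05)
#' @param calibration \code{"ftest"} (default, small-sample calibrated) or
#'   \code{"chisq"} (asymptotic)
#' @return a \code{DataFrame} with one row per tested transcript:
#'   \code{lrtStat}, \code{df}, \code{pvalue}, \code{fdr}, \code{isDet},
#'   \code{dispersion}, \code{momFallback} and fitted per-group normalized
#'   means; excluded all-zero transcripts are listed in
#'   \code{metadata(result)$excluded}
#' @export
nbLRT <- function(x, sizeFactors = medianRatioSizeFactors(x), detFdr = 0.05,
                  calibration = c("ftest", "chisq")) {
  calibration <- match.arg(calibration)
  stopifnot(is(x, "TimecourseExperiment"))
  time <- droplevels(timeLabels(x))
  if (nlevels(time) < 2) stop("need >= 2 time groups")
  if (any(table(time) < 2)) stop("need >= 2 samples per group")
  m <- counts(x)
  sf <- sizeFactors
  zero <- rowSums(m) == 0
  if (any(zero))
    message(sum(zero), " all-zero transcript(s) excluded from testing")
  m <- m[!zero, , drop = FALSE]
  groupIdx <- split(seq_len(ncol(m)), time)
  k <- length(groupIdx)
  nTr <- nrow(m)
  stat <- disp <- numeric(nTr)
  mom <- logical(nTr)
  qmat <- matrix(NA_real_, nTr, k, dimnames = list(NULL, names(groupIdx)))
  for (g in seq_len(nTr)) {
    y <- m[g, ]
    fit <- tryCatch({
      opt <- stats::optimize(function(la) .nbProfileLL(y, sf, groupIdx, exp(la)),
                             lower = log(1e-8), upper = log(50),
                             maximum = TRUE, tol = 1e-4)
      list(alpha = max(exp(opt$maximum), 1e-8), fallback = FALSE)
    }, error = function(e) list(alpha = .momDispersion(y, sf), fallback = TRUE))
    a <- fit$alpha
    full <- lapply(groupIdx, function(ix) .nbFitGroup(y[ix], sf[ix], a))
    llFull <- sum(vapply(full, `[[`, 0, "ll"))
    llRed <- .nbFitGroup(y, sf, a)$ll
    stat[g] <- max(0, 2 * (llFull - llRed))
    disp[g] <- a
    mom[g] <- fit$fallback
    qmat[g, ] <- vapply(full, `[[`, 0, "q")
  }
  p <- if (calibration == "ftest")
    stats::pf(stat / (k - 1), k - 1, ncol(m) - k, lower.tail = FALSE)
  else stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  fdr <- bhAdjust(p)
  res <- S4Vectors::DataFrame(
    transcript = rownames(m), lrtStat = stat, df = rep(k - 1L, nTr),
    pvalue = p, fdr = fdr, isDet = fdr < detFdr,
    dispersion = disp, momFallback = mom)
  for (gn in colnames(qmat)) res[[paste0("mean_", gn)]] <- qmat[, gn]
  rownames(res) <- rownames(m)
  S4Vectors::metadata(res) <- list(excluded = rownames(counts(x))[zero],
                                   detFdr = detFdr)
  res
}

#' Transcripts flagged as differentially expressed
#' @param detable result of \code{\link{nbLRT}}
#' @return character vector of DET ids
#' @export
detTranscripts <- function(detable) {
  detable$transcript[detable$isDet]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over \code{stats::p.adjust(method = "BH")}:
#' adjusted_i = min over j with p_(j) >= p_(i) of p_(j) m / j, capped at 1,
#' returned in input order.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted p-values, same order as input
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Variance-stabilizing transform (log2 of normalized counts)
#'
#' \code{log2(count / sizeFactor + 1)}: monotone in counts, zero at zero
#' count.  This is a simple stand-in for model-based variance stabilization
#' and is not byte-equivalent to any external tool's transform.
#'
#' @param x a \linkS4class{TimecourseExperiment} or count matrix
#' @param sizeFactors positive per-sample size factors
#' @return matrix of transformed values with attribute
#'   \code{provenance = "log2-sizefactor-pseudocount"}
#' @export
vstCounts <- function(x, sizeFactors = medianRatioSizeFactors(x)) {
  m <- if (is(x, "TimecourseExperiment")) counts(x) else as.matrix(x)
  if (any(sizeFactors <= 0)) stop("size factors must be positive")
  out <- log2(sweep(m, 2, sizeFactors, "/") + 1)
  attr(out, "provenance") <- "log2-sizefactor-pseudocount"
  out
}

#' PCA embedding of samples
#'
#' Transcripts are centered; samples are projected on the leading principal
#' components.
#'
#' @param expr transcripts x samples expression matrix (e.g. from
#'   \code{\link{vstCounts}})
#' @param nComponents number of components to return
#' @return list with \code{scores} (samples x components) and
#'   \code{varianceFraction} (non-increasing, sums to <= 1)
#' @export
pcaEmbedding <- function(expr, nComponents = 2) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("need >= 2 samples")
  if (nComponents > min(dim(expr)))
    stop("nComponents exceeds min(dim(expr))")
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(nComponents), drop = FALSE],
       varianceFraction = vf[seq_len(nComponents)])
}

#' Minimal per-group sample size for one-way ANOVA power
#'
#' Smallest n per group such that the noncentral-F power with df1 = k - 1,
#' df2 = k n - k and noncentrality f^2 k n reaches the requested power at
#' level alpha.
#'
#' @param effectF Cohen's f effect size (> 0)
#' @param alpha significance level
#' @param power target power (1 - beta)
#' @param kGroups number of groups (>= 2)
#' @return minimal integer n per group
#' @examples
#' powerSampleSize(0.7, alpha = 0.05, power = 0.8, kGroups = 3)  # 8
#' @export
powerSampleSize <- function(effectF, alpha = 0.05, power = 0.8, kGroups = 3) {
  stopifnot(effectF > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            kGroups >= 2)
  for (n in 2:1e6) {
    df1 <- kGroups - 1
    df2 <- kGroups * n - kGroups
    lambda <- effectF^2 * kGroups * n
    pw <- 1 - stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda)
    if (pw >= power) return(n)
  }
  stop("requested power not reachable within n <= 1e6")
}
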