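## Independent oracles used across the suite.  These deliberately avoid the
## package's code paths: direct formulas, enumeration, and pair counting.

## exact upper-tail hypergeometric by direct tail summation over overlaps
oracleHyperTail <- function(x, termSize, setSize, universeSize) {
  i <- x:min(termSize, setSize)
  sum(choose(termSize, i) * choose(universeSize - termSize, setSize - i)) /
    choose(universeSize, setSize)
}

## literal enumeration of every possible draw (small universes only)
oracleHyperEnumerate <- function(x, term, universe, setSize) {
  draws <- utils::combn(universe, setSize, simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, term)) >= x, TRUE))
}

## BH step-up by its definition: min over j >= rank of p_(j) * m / j
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  ranked <- p[o] * m / seq_len(m)
  adj[o] <- rev(cummin(rev(ranked)))
  pmin(adj, 1)
}

## adjusted Rand index by pair counting
oracleARI <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  np <- choose(sum(tab), 2)
  expected <- ai * bj / np
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

## brute-force NB grouped-means LRT p-value via grid/optimize maximization
## of the plain likelihood (independent parametrization: optimize over mu)
oracleNbLrtChisqP <- function(counts, groups) {
  groupLL <- function(y, alpha) {
    if (sum(y) == 0) return(0)
    f <- function(mu) sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
    opt <- optimize(f, interval = c(max(mean(y) / 50, 1e-6), mean(y) * 50 + 1),
                    maximum = TRUE, tol = 1e-9)
    opt$objective
  }
  alphas <- exp(seq(log(1e-8), log(5), length.out = 120))
  fullLL <- vapply(alphas, function(a)
    sum(vapply(split(counts, groups), groupLL, 0, alpha = a)), 0)
  aHat <- alphas[which.max(fullLL)]
  llF <- max(fullLL)
  llR <- groupLL(counts, aHat)
  stat <- max(0, 2 * (llF - llR))
  pchisq(stat, df = length(unique(groups)) - 1, lower.tail = FALSE)
}

## one-way ANOVA power scan over n (noncentral F, direct evaluation)
oraclePowerScan <- function(f, alpha, power, k, nMax = 50) {
  for (n in 2:nMax) {
    df1 <- k - 1
    df2 <- k * n - k
    pw <- 1 - pf(qf(1 - alpha, df1, df2), df1, df2, ncp = f^2 * k * n)
    if (pw >= power) return(n)
  }
  NA_integer_
}

## direct TOM formula with explicit loops (signed adjacency)
oracleTom <- function(expr, beta) {
  n <- nrow(expr)
  a <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    a[i, j] <- ((1 + cor(expr[i, ], expr[j, ])) / 2)^beta
  diag(a) <- 1
  k <- rowSums(a) - 1
  tom <- diag(n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

## small helper: default simulated study shared by several tests
simulatedStudy <- function(seed = 1, nTranscripts = 2000) {
  runPipeline(defaultPipelineConfig(seed = seed))
}
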