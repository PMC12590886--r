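# Independent brute-force oracles and small fixtures used across tests.

# Step-by-step Benjamini-Hochberg: sorted p * m / i, cumulative min from the
# largest p, capped at 1, mapped back to input order.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Literal 2-LOD-drop rule: retain lod > peak - drop, span the contiguous
# retained run containing the peak (or all retained positions).
lodOracle <- function(pos, lod, drop = 2, spanAll = FALSE) {
  peak <- which.max(lod)
  keep <- lod > lod[peak] - drop
  if (spanAll) return(range(pos[keep]))
  lo <- peak
  while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- peak
  while (hi < length(pos) && keep[hi + 1]) hi <- hi + 1
  c(pos[lo], pos[hi])
}

# Triple-loop topological overlap.
tomOracle <- function(a) {
  n <- nrow(a)
  k <- colSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Pair-counting adjusted Rand index (independent of any package).
ariOracle <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  a <- comb2(as.vector(tab))
  b <- comb2(rowSums(tab))
  c2 <- comb2(colSums(tab))
  tot <- n * (n - 1) / 2
  expected <- b * c2 / tot
  (a - expected) / ((b + c2) / 2 - expected)
}

# Small covariate fixture: n samples, two sexes, three batches.
makeCov <- function(n, seed = 1, trait = rep(NA_real_, n)) {
  set.seed(seed)
  SampleCovariates(sprintf("s%02d", seq_len(n)),
                   sex = sample(c("m", "f"), n, replace = TRUE),
                   batch = sample(paste0("b", 1:3), n, replace = TRUE),
                   weight = rnorm(n, 70, 5), trait = trait)
}

# Config for a cohort with no planted structure at all (null calibration).
nullConfig <- function(seed, n = 79, nSnps = 100, nGenes = 100,
                       nOutliers = 0) {
  simulationConfig(nSamples = n, nSnps = nSnps, nGenes = nGenes,
                   eqtlPlan = data.frame(), transPlan = data.frame(),
                   modulePlan = list(), nOutliers = nOutliers, seed = seed)
}

# Config with three orthogonal planted modules and nothing else.
moduleConfig <- function(seed, nSamples = 70, perModule = 100) {
  g <- function(a, b) sprintf("gene%03d", a:b)
  simulationConfig(
    nSamples = nSamples, nGenes = 3 * perModule, nSnps = 60,
    eqtlPlan = data.frame(), transPlan = data.frame(),
    modulePlan = list(
      m1 = list(genes = g(1, perModule), driver = NULL, loading = 1),
      m2 = list(genes = g(perModule + 1, 2 * perModule), driver = NULL,
                loading = 1),
      m3 = list(genes = g(2 * perModule + 1, 3 * perModule), driver = NULL,
                loading = 1)),
    nOutliers = 0, seed = seed)
}
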