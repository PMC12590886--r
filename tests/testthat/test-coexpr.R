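test_that("an extreme sample is flagged as outlier; homogeneous data is not", {
  set.seed(20)
  m <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  m[, "s7"] <- m[, "s7"] + 50
  expr <- ExpressionMatrix(m, scale = "normalized")
  out <- detectOutlierSamples(expr)
  expect_identical(out$removed, "s7")

  m2 <- m[, colnames(m) != "s7"]
  out2 <- detectOutlierSamples(ExpressionMatrix(m2, scale = "normalized"),
                               cutHeight = 1e6)
  expect_identical(length(out2$removed), 0L)
  expect_error(detectOutlierSamples(expr[, 1:5]), "10 samples")
})

test_that("planted outlier samples are exactly recovered", {
  cfg <- simulationConfig(seed = 21)
  g <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  expr <- simulateExpression(g, cov, cfg)
  out <- detectOutlierSamples(filterExpressed(expr)$expr)
  expect_setequal(out$removed, simulationLayout(cfg)$outlierSamples)
})

test_that("TOM matches the closed form on edge cases and random instances", {
  # two genes with identical binary adjacency rows and a_ij = 1
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1
  a[1, 3] <- a[3, 1] <- a[2, 3] <- a[3, 2] <- 1
  tom <- tomSimilarity(a)
  expect_equal(tom[1, 2], 1)
  # no direct edge, no shared neighbours -> 0
  b <- matrix(0, 4, 4)
  b[3, 4] <- b[4, 3] <- 0.5
  expect_equal(tomSimilarity(b)[1, 2], 0)
  # brute-force formula on random instances up to 20 genes
  set.seed(22)
  for (n in c(5, 6, 12, 20)) {
    x <- matrix(runif(n * n, 0, 0.9), n, n)
    x <- (x + t(x)) / 2
    diag(x) <- 0
    expect_equal(tomSimilarity(x), tomOracle(x), tolerance = 1e-10)
  }
  expect_error(tomSimilarity(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("module eigengene matches an independent eigen decomposition", {
  set.seed(23)
  m <- matrix(rnorm(5 * 15), 5, 15,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:15)))
  e <- moduleEigengene(m)
  ms <- t(scale(t(m)))
  ms <- ms * sqrt(15 / 14)  # moduleEigengene standardizes by sd
  ev <- eigen(crossprod(ms))$vectors[, 1]
  expect_equal(abs(drop(crossprod(e, ev))), 1, tolerance = 1e-8)
  expect_equal(sum(e^2), 1, tolerance = 1e-12)
  # sign equivariance: flipping all member genes flips the eigengene
  e2 <- moduleEigengene(-m)
  expect_equal(e2, -e, tolerance = 1e-10)
  # identical standardized genes: eigengene carries all the variance
  one <- matrix(rep(rnorm(10), 3), 3, 10, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:10)))
  e3 <- moduleEigengene(one)
  expect_equal(abs(cor(e3, one[1, ])), 1, tolerance = 1e-10)
})

test_that("planted orthogonal modules are recovered by the static cut", {
  cfg <- moduleConfig(seed = 30)
  g <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  expr <- simulateExpression(g, cov, cfg)
  tom <- tomSimilarity(adjacencyMatrix(expr, pickSoftPower(expr)$power))
  ma <- cutModules(tom, expr)
  planted <- rep(1:3, each = 100)
  expect_gte(ariOracle(moduleLabels(ma), planted), 0.9)
  # a duplicated gene lands in the same module as its original
  m <- log2(exprValues(expr) + 1)
  m2 <- rbind(m, dup = m["gene001", ])
  tom2 <- tomSimilarity(adjacencyMatrix(m2, 6))
  ma2 <- cutModules(tom2, m2)
  expect_identical(unname(moduleLabels(ma2)["dup"]),
                   unname(moduleLabels(ma2)["gene001"]))
})

test_that("module labels are invariant to gene input order", {
  cfg <- moduleConfig(seed = 31, perModule = 50)
  g <- simulateGenotypes(cfg)
  expr <- simulateExpression(g, simulateCovariates(cfg), cfg)
  m <- log2(exprValues(expr) + 1)
  tom <- tomSimilarity(adjacencyMatrix(m, 8))
  ma <- cutModules(tom, m)
  set.seed(31)
  perm <- sample(nrow(m))
  tomP <- tomSimilarity(adjacencyMatrix(m[perm, ], 8))
  maP <- cutModules(tomP, m[perm, ])
  lab <- moduleLabels(ma)
  labP <- moduleLabels(maP)[names(lab)]
  expect_equal(ariOracle(lab, labP), 1, tolerance = 1e-12)
})

test_that("tiny inputs fall back to unassigned", {
  set.seed(24)
  m <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  a <- adjacencyMatrix(m, 2)
  expect_warning(ma <- cutModules(tomSimilarity(a), m, minModuleSize = 30),
                 "unassigned")
  expect_true(all(moduleLabels(ma) == "unassigned"))
})

test_that("soft power choice is deterministic and respects the target", {
  cfg <- moduleConfig(seed = 32, perModule = 40)
  expr <- simulateExpression(simulateGenotypes(cfg),
                             simulateCovariates(cfg), cfg)
  p1 <- pickSoftPower(expr)
  p2 <- pickSoftPower(expr)
  expect_identical(p1$power, p2$power)
  expect_identical(pickSoftPower(expr, r2Target = 0)$power, 1L)
  expect_error(pickSoftPower(exprValues(expr)[1:10, ]), "50")
})

test_that("module-trait statistics match the two-pass Pearson oracle", {
  cfg <- moduleConfig(seed = 33, perModule = 40)
  g <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  expr <- simulateExpression(g, cov, cfg)
  tom <- tomSimilarity(adjacencyMatrix(expr, 6))
  ma <- cutModules(tom, expr)
  set.seed(33)
  E <- eigengenes(ma)
  trait <- E[, 1] * 2 + rnorm(nrow(E), sd = 0.5) + 7
  mtr <- moduleTraitRelationships(ma, trait)
  twoPass <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (k in seq_len(ncol(E)))
    expect_equal(mtr$r[mtr$module == colnames(E)[k]],
                 twoPass(E[, k], trait), tolerance = 1e-12)
  # trait equal to an eigengene: r = 1, p ~ 0
  mtr1 <- moduleTraitRelationships(ma, E[, 1])
  expect_equal(mtr1$r[mtr1$module == colnames(E)[1]], 1, tolerance = 1e-12)
  expect_lt(mtr1$p[mtr1$module == colnames(E)[1]], 1e-30)
  expect_error(moduleTraitRelationships(ma, rep(1, nrow(E))), "constant")
  # GS/MM criticality wiring
  ma2 <- analyzeModules(expr, ma, trait)
  gsTab <- geneStats(ma2)
  sigMods <- moduleTrait(ma2)$module[moduleTrait(ma2)$p < 0.01]
  expect_identical(gsTab$critical,
                   gsTab$module %in% sigMods & !is.na(gsTab$mm_p) &
                     gsTab$gs_p < 0.01 & gsTab$mm_p < 0.01)
})
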