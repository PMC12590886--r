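test_that("the generator is deterministic given one seed", {
  cfg <- simulationConfig(nSamples = 20, nSnps = 24, nGenes = 20, seed = 11)
  g1 <- simulateGenotypes(cfg)
  g2 <- simulateGenotypes(cfg)
  expect_identical(dosage(g1), dosage(g2))
  cov <- simulateCovariates(cfg)
  e1 <- simulateExpression(g1, cov, cfg)
  e2 <- simulateExpression(g2, simulateCovariates(cfg), cfg)
  expect_identical(exprValues(e1), exprValues(e2))
  t1 <- simulateTrait(e1, cov, cfg)
  t2 <- simulateTrait(e2, cov, cfg)
  expect_identical(traitValues(t1), traitValues(t2))
})

test_that("perfect haplotype copying gives pairwise dosage r2 of 1", {
  cfg <- simulationConfig(nSamples = 40, nSnps = 5, nGenes = 5,
                          chroms = "1", ldBlockSize = 5, ldWithinR = 1,
                          missingRate = 0, eqtlPlan = data.frame(),
                          transPlan = data.frame(), modulePlan = list(),
                          nOutliers = 0, seed = 4)
  g <- simulateGenotypes(cfg)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(ldR2(g, i, j), 1, tolerance = 1e-12)
})

test_that("independent SNPs have null-level r2 (Monte-Carlo expectation)", {
  n <- 100
  r2s <- unlist(lapply(1:8, function(s) {
    cfg <- simulationConfig(nSamples = n, nSnps = 20, nGenes = 5,
                            chroms = "1", ldBlockSize = 1, missingRate = 0,
                            mafRange = c(0.2, 0.5), eqtlPlan = data.frame(),
                            transPlan = data.frame(), modulePlan = list(),
                            nOutliers = 0, seed = s)
    cc <- cor(dosage(simulateGenotypes(cfg)))^2
    cc[upper.tri(cc)]
  }))
  # E[r2] under independence is ~ 1/(n-1)
  expect_equal(mean(r2s), 1 / (n - 1), tolerance = 0.35)
})

test_that("planted SNPs marked retained satisfy the MAF floor", {
  out <- makeDataset(simulationConfig(nSamples = 50, nSnps = 60,
                                      nGenes = 40, seed = 5),
                     tempfile("ds"))
  plan <- out$truth$eqtl_plan
  expect_true(all(plan$retained))
  expect_true(all(plan$realized_maf >= 0.05))
})

test_that("noise-free trait with pure regulator effect gives adjusted r = -1", {
  cfg <- simulationConfig(
    nSamples = 30, nSnps = 16, nGenes = 10, chroms = "1",
    modulePlan = list(), transPlan = data.frame(), nOutliers = 0,
    traitNoiseSd = 0, regulatorEffect = -1,
    traitCovariateEffects = list(sex = 0, batchSd = 0, weightSlope = 0),
    seed = 6)
  g <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  expr <- simulateExpression(g, cov, cfg)
  cov <- simulateTrait(expr, cov, cfg)
  reg <- simulationLayout(cfg)$regulatorGene
  x <- adjustCovariates(latentValues(expr)[reg, ], cov)
  y <- adjustCovariates(traitValues(cov), cov)
  expect_equal(cor(x, y), -1, tolerance = 1e-10)
})

test_that("a null regulator effect leaves the regulator non-significant", {
  hits <- vapply(1:20, function(s) {
    cfg <- simulationConfig(nSamples = 60, nSnps = 30, nGenes = 60,
                            regulatorEffect = 0, nOutliers = 0, seed = s)
    g <- simulateGenotypes(cfg)
    cov <- simulateCovariates(cfg)
    expr <- simulateExpression(g, cov, cfg)
    cov <- simulateTrait(expr, cov, cfg)
    tab <- traitCorrelation(expr, cov)
    tab$significant[tab$gene_id == simulationLayout(cfg)$regulatorGene]
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("stronger planted effects give monotone median association signal", {
  medLod <- vapply(c(0.5, 1.5, 3), function(beta) {
    lods <- vapply(1:5, function(s) {
      cfg <- simulationConfig(nSamples = 60, nSnps = 16, nGenes = 8,
                              chroms = "1",
                              eqtlPlan = data.frame(snp = 4, gene = 3,
                                                    beta = beta),
                              transPlan = data.frame(),
                              modulePlan = list(), nOutliers = 0, seed = s)
      g <- simulateGenotypes(cfg)
      cov <- simulateCovariates(cfg)
      expr <- simulateExpression(g, cov, cfg)
      lay <- simulationLayout(cfg)
      norm <- rankInverseNormal(expr)
      fit <- fitAssociation(exprValues(norm)[lay$eqtlPlan$gene[1], ],
                            dosage(g)[, lay$eqtlPlan$snp[1]], cov)
      -log10(fit$p)
    }, numeric(1))
    median(lods)
  }, numeric(1))
  expect_true(all(diff(medLod) > 0))
})

test_that("makeDataset writes the five data files plus ground truth", {
  dir <- tempfile("ds")
  out <- makeDataset(simulationConfig(nSamples = 40, nSnps = 40,
                                      nGenes = 30, seed = 9), dir)
  expect_true(all(file.exists(unlist(out$paths))))
  # fitted beta consistent with planted beta within 3 SE (latent scale)
  lay <- simulationLayout(simulationConfig(nSamples = 40, nSnps = 40,
                                           nGenes = 30, seed = 9))
  lat <- latentValues(out$expression)
  for (k in seq_len(nrow(lay$eqtlPlan))) {
    fit <- fitAssociation(lat[lay$eqtlPlan$gene[k], ],
                          dosage(out$genotypes)[, lay$eqtlPlan$snp[k]],
                          out$covariates)
    expect_lt(abs(fit$beta - lay$eqtlPlan$beta[k]), 3 * fit$se)
  }
  # re-run with the same seed: identical numeric content
  dir2 <- tempfile("ds")
  makeDataset(simulationConfig(nSamples = 40, nSnps = 40, nGenes = 30,
                               seed = 9), dir2)
  expect_identical(readLines(file.path(dir, "expression.tsv")),
                   readLines(file.path(dir2, "expression.tsv")))
  expect_identical(readLines(file.path(dir, "genotypes.vcf")),
                   readLines(file.path(dir2, "genotypes.vcf")))
})
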