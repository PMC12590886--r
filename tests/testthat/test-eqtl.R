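test_that("genotype QC keeps boundary values and drops non-chromosomal SNPs", {
  # 10 samples x 10 SNPs (5 fillers keep individual missing rates at 0.1)
  d <- matrix(rep(c(0, 1, 2), length.out = 100), 10, 10,
              dimnames = list(sprintf("s%02d", 1:10),
                              c(paste0("v", 1:5), paste0("f", 6:10))))
  d[, 1] <- 0; d[1, 1] <- 1             # v1: MAF 0.05 exactly -> retained
  d[, 2] <- 0                           # v2: monomorphic -> dropped
  d[, 3] <- rep(0:1, 5); d[1, 3] <- NA  # v3: missing rate 0.1 -> retained
  d[, 4] <- rep(0:1, 5)
  d[2, 4] <- NA; d[3, 4] <- NA          # v4: missing rate 0.2 -> dropped
  d[, 5] <- rep(c(0, 2), 5)             # v5: fine but on scaffold -> dropped
  g <- GenotypeMatrix(d, chrom = c("1", "1", "2", "2", "scaffold_12",
                                   rep("3", 5)),
                      pos = c(100, 200, 100, 200, 100, 1:5 * 100))
  qc <- qcGenotypes(g)
  expect_setequal(snpIds(qc$genotypes), c("v1", "v3", paste0("f", 6:10)))
  expect_identical(qc$report$n_samples_out, 10L)
  expect_identical(unname(qc$report$removed["nonchromosomal"]), 1L)

  # mitochondrial contig dropped; individual filter applied first
  d2 <- matrix(1, 10, 2, dimnames = list(sprintf("s%02d", 1:10),
                                         c("m1", "a1")))
  d2[1, ] <- NA                     # sample 1: 100% missing -> removed
  g2 <- GenotypeMatrix(d2, chrom = c("MT", "1"), pos = c(1, 1))
  qc2 <- qcGenotypes(g2)
  expect_identical(qc2$report$n_samples_out, 9L)
  expect_false("m1" %in% snpIds(qc2$genotypes))
})

test_that("fitAssociation recovers a noiseless effect exactly", {
  n <- 24
  cov <- makeCov(n)
  S <- rep(c(0, 1, 2), length.out = n)
  g <- 2 + 1.5 * S
  fit <- fitAssociation(g, S, cov)
  expect_equal(fit$beta, 1.5, tolerance = 1e-10)
  expect_lt(fit$p, 1e-20)
})

test_that("fitAssociation matches lm and the Frisch-Waugh oracle", {
  set.seed(8)
  n <- 40
  cov <- makeCov(n, seed = 8)
  S <- sample(0:2, n, replace = TRUE)
  g <- 0.6 * S + rnorm(n)
  fit <- fitAssociation(g, S, cov)
  ref <- summary(lm(g ~ sex + batch + weight + S,
                    data = covariateTable(cov)))$coefficients["S", ]
  expect_equal(fit$beta, unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(fit$se, unname(ref["Std. Error"]), tolerance = 1e-10)
  expect_equal(fit$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
  # partialled regression: residualize both sides on covariates
  X <- model.matrix(~ sex + batch + weight, covariateTable(cov))
  b <- coef(lm(qr.resid(qr(X), g) ~ qr.resid(qr(X), S)))[2]
  expect_equal(fit$beta, unname(b), tolerance = 1e-10)
})

test_that("fitAssociation is equivariant to joint sample permutation", {
  set.seed(9)
  n <- 30
  cov <- makeCov(n, seed = 9)
  S <- sample(0:2, n, replace = TRUE)
  g <- 0.4 * S + rnorm(n)
  fit1 <- fitAssociation(g, S, cov)
  perm <- sample(n)
  fit2 <- fitAssociation(g[perm], S[perm], cov[perm])
  expect_equal(fit1, fit2, tolerance = 1e-12)
})

test_that("fitAssociation handles constant and missing dosages", {
  n <- 20
  cov <- makeCov(n)
  g <- rnorm(n)
  expect_message(out <- fitAssociation(g, rep(1, n), cov), "constant")
  expect_null(out)
  S <- rep(c(0, 1, 2, NA), 5)
  expect_identical(fitAssociation(g, S, cov)$n_used, 20L)       # imputed
  expect_identical(fitAssociation(g, S, cov,
                                  missing = "complete")$n_used, 15L)
  expect_error(fitAssociation(g[1:5], S[1:5], cov[1:5]), "fewer than")
})

test_that("cis/trans classification is boundary-inclusive at 1 Mb", {
  expect_identical(classifyRelation("1", 2e6, "1", 1e6), "cis")
  expect_identical(classifyRelation("1", 2e6 + 1, "1", 1e6), "trans")
  expect_identical(classifyRelation("1", 1e6, "2", 1e6), "trans")
  expect_identical(classifyRelation("1", 2e6, "1", 1e6, inclusive = FALSE),
                   "trans")
})

test_that("bhFdr matches the hand-computed example and BH properties", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bhFdr(0.37), 0.37)
  set.seed(10)
  p <- runif(50)
  q <- bhFdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # isotonic in p
  expect_true(all(q <= 1) && all(q >= p))
  expect_error(bhFdr(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("eqtlScan flags planted signals and applies strict thresholds", {
  cfg <- simulationConfig(nSamples = 60, nSnps = 40, nGenes = 20,
                          noiseSd = 0.4, nOutliers = 0, modulePlan = list(),
                          seed = 12)
  g <- simulateGenotypes(cfg)
  cov <- simulateCovariates(cfg)
  expr <- simulateExpression(g, cov, cfg)
  lay <- simulationLayout(cfg)
  qc <- qcGenotypes(g)
  norm <- rankInverseNormal(filterExpressed(expr)$expr)
  scan <- eqtlScan(norm, qc$genotypes, cov)
  reg <- lay$regulatorGene
  regSnp <- lay$eqtlPlan$snp[lay$eqtlPlan$gene == reg]
  hit <- scan[scan$gene_id == reg & scan$snp_id == regSnp, ]
  expect_identical(nrow(hit), 1L)
  expect_true(hit$significant_gw)
  expect_true(all(scan$relation == "cis"))
  # flags are strict "<" comparisons of p against the thresholds
  expect_identical(scan$significant_gw, scan$p < 5e-8)
  expect_identical(scan$significant_sugg, scan$p < 5e-6)
  # tighter threshold yields a subset of flagged genes
  expect_true(all(scan$gene_id[scan$significant_gw] %in%
                    scan$gene_id[scan$significant_sugg]))
  expect_error(eqtlScan(norm[0, ], qc$genotypes, cov), "empty")
})

test_that("eqtlScan warns and returns empty when no cis pairs exist", {
  m <- matrix(rnorm(20), 2, 10,
              dimnames = list(c("g1", "g2"), sprintf("s%02d", 1:10)))
  info <- data.frame(chrom = c("7", "7"), start = c(1e6, 2e6),
                     end = c(1e6 + 100, 2e6 + 100), strand = c("+", "+"),
                     row.names = c("g1", "g2"))
  expr <- ExpressionMatrix(m, geneInfo = info, scale = "normalized")
  d <- matrix(rep(0:2, length.out = 20), 10, 2,
              dimnames = list(sprintf("s%02d", 1:10), c("v1", "v2")))
  geno <- GenotypeMatrix(d, chrom = c("1", "1"), pos = c(1e6, 2e6))
  expect_warning(scan <- eqtlScan(expr, geno, makeCov(10)), "no cis")
  expect_identical(nrow(scan), 0L)
})
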