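mkGwas <- function(posMb, lod, chrom = "9") {
  GwasSummary(rep(chrom, length(posMb)), posMb * 1e6, 10^(-lod))
}

test_that("2-LOD interval matches the worked profiles", {
  iv <- lodDropInterval(mkGwas(1:5, c(1, 3, 7, 4, 2)))
  expect_equal(GenomicRanges::start(iv), 3e6)
  expect_equal(GenomicRanges::end(iv), 3e6)
  expect_equal(S4Vectors::mcols(iv)$n_retained, 1L)

  iv2 <- lodDropInterval(mkGwas(1:5, c(6, 6.5, 7, 6.5, 1)))
  expect_equal(GenomicRanges::start(iv2), 1e6)
  expect_equal(GenomicRanges::end(iv2), 4e6)

  # flat profile: peak - 2 is below everything, whole chromosome retained
  iv3 <- lodDropInterval(mkGwas(1:6, rep(3, 6)))
  expect_equal(GenomicRanges::start(iv3), 1e6)
  expect_equal(GenomicRanges::end(iv3), 6e6)
  expect_error(lodDropInterval(GwasSummary(character(), numeric(),
                                           numeric())), "empty")
})

test_that("2-LOD interval equals the brute-force rule on random profiles", {
  set.seed(13)
  for (rep in 1:300) {
    k <- sample(3:40, 1)
    pos <- sort(sample(1:500, k)) * 1e4
    lod <- round(runif(k, 0, 12), 2)
    gw <- GwasSummary(rep("2", k), pos, 10^(-lod))
    for (spanAll in c(FALSE, TRUE)) {
      iv <- lodDropInterval(gw, drop = 2, spanAll = spanAll)
      expect_identical(c(GenomicRanges::start(iv), GenomicRanges::end(iv)),
                       as.integer(lodOracle(pos, lod, 2, spanAll)))
    }
  }
})

test_that("ld r2 handles perfect, inverted and monomorphic dosages", {
  d <- cbind(a = c(0, 0, 1, 1, 2, 2), b = c(2, 2, 1, 1, 0, 0),
             c = c(0, 0, 1, 1, 2, 2), mono = rep(1, 6))
  rownames(d) <- paste0("s", 1:6)
  g <- GenotypeMatrix(d, chrom = rep("1", 4), pos = 1:4)
  expect_equal(ldR2(g, "a", "c"), 1)
  expect_equal(ldR2(g, "a", "b"), 1)   # perfect negative correlation
  expect_warning(r <- ldR2(g, "a", "mono"), "monomorphic")
  expect_true(is.na(r))
})

test_that("LD blocks recover planted blocks and satisfy the all-pairs rule", {
  cfg <- simulationConfig(nSamples = 60, nSnps = 24, nGenes = 10,
                          chroms = "1", ldBlockSize = 6, ldWithinR = 1,
                          missingRate = 0, eqtlPlan = data.frame(),
                          transPlan = data.frame(), modulePlan = list(),
                          nOutliers = 0, seed = 14)
  g <- simulateGenotypes(cfg)
  blocks <- findLdBlocks(g)
  lay <- simulationLayout(cfg)
  expect_identical(lapply(blocks$snps, identity), unname(lay$blocks))
  # re-verify the all-pairs predicate directly
  for (b in blocks$snps) {
    ix <- match(b, snpIds(g))
    for (i in seq_along(ix)[-1]) for (j in seq_len(i - 1))
      expect_gt(ldR2(g, ix[i], ix[j]), 0.90)
  }
  # blocks are disjoint and ordered along the map
  expect_false(anyDuplicated(unlist(blocks$snps)) > 0)
  expect_true(all(diff(blocks$start_pos) > 0))
})

test_that("colocalization counts inclusive boundaries and ranks by overlap", {
  recs <- data.frame(
    snp_id = c("v1", "v2", "v3", "v4"),
    gene_id = c("gA", "gA", "gA", "gB"),
    chrom_snp = "9", pos_snp = c(100, 500, 501, 200),
    chrom_gene = "9", tss = 150,
    beta = 1, se = 0.1, t = 10, p = 1e-9, n_used = 50L, q = 1e-8,
    relation = "cis", significant_gw = TRUE, significant_sugg = TRUE,
    stringsAsFactors = FALSE)
  iv <- genomicInterval("9", 100, 500)
  rep <- colocalize(iv, recs)
  expect_identical(rep$gene_id, c("gA", "gB"))
  expect_identical(rep$n_coloc, c(2L, 1L))          # v3 at 501 excluded
  expect_true("v2" %in% rep$snps[[1]])              # boundary SNP counted
  # disjoint interval: nothing
  expect_identical(nrow(colocalize(genomicInterval("9", 1e4, 2e4), recs)), 0L)
})

test_that("permutation p attains the add-one lower bound exactly", {
  set.seed(15)
  n <- 40
  cov <- makeCov(n, seed = 15)
  S <- rep(0:2, length.out = n)
  trait <- 5 * S + rnorm(n, sd = 0.1)
  cov <- SampleCovariates(sampleIds(cov), covariateTable(cov)$sex,
                          covariateTable(cov)$batch,
                          covariateTable(cov)$weight, trait)
  d <- matrix(S, n, 1, dimnames = list(sampleIds(cov), "v1"))
  res <- permutationAssoc(d, cov, nPerm = 99, seed = 1)
  expect_identical(res$p_pointwise, 1 / 100)
  expect_identical(res$p_familywise, 1 / 100)
})

test_that("duplicated SNP columns get identical empirical p-values", {
  set.seed(16)
  n <- 30
  trait <- rnorm(n)
  cov <- makeCov(n, seed = 16, trait = trait)
  S <- sample(0:2, n, replace = TRUE)
  d <- cbind(v1 = S, v2 = S, v3 = sample(0:2, n, replace = TRUE))
  rownames(d) <- sampleIds(cov)
  res <- permutationAssoc(d, cov, nPerm = 200, seed = 2)
  expect_identical(res$p_pointwise[1], res$p_pointwise[2])
  expect_identical(res$p_familywise[1], res$p_familywise[2])
  # family-wise p dominates pointwise p for every SNP
  expect_true(all(res$p_familywise >= res$p_pointwise))
})

test_that("null permutation p-values are roughly uniform", {
  ps <- vapply(1:60, function(s) {
    set.seed(100 + s)
    n <- 30
    cov <- makeCov(n, seed = 100 + s, trait = rnorm(n))
    d <- matrix(sample(0:2, n, replace = TRUE), n, 1,
                dimnames = list(sampleIds(cov), "v1"))
    permutationAssoc(d, cov, nPerm = 99, seed = s)$p_pointwise
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("genotype-stratified summary reports means, SEs and the t-test", {
  S <- c(0, 0, 0, 1, 1, 1, 2)
  trait <- c(1, 2, 3, 7, 8, 9, 5)
  out <- genotypeStratifiedTest(S, trait)
  expect_equal(out$stats$mean, c(2, 8, 5))
  expect_equal(out$stats$se[1], 1 / sqrt(3))
  expect_true(is.na(out$stats$se[3]))               # singleton: mean only
  expect_setequal(out$test$groups, c("0", "1"))
  expect_equal(out$test$p,
               t.test(trait[S == 0], trait[S == 1], var.equal = TRUE)$p.value)
  # identical within, different between -> essentially zero p
  out2 <- genotypeStratifiedTest(rep(c(0, 2), each = 4),
                                 rep(c(1, 9), each = 4) +
                                   rep(c(-1e-6, 1e-6), 4))
  expect_lt(out2$test$p, 1e-10)
  expect_error(genotypeStratifiedTest(c(0, 1, 1), c(1, 2, 3)),
               "two genotype classes")
})
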