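#' @include dataio.R
NULL

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the motivating study design: 79 animals (58:21 sex
#' split, 11 slaughter batches, carcass weight ~ N(71.20, 6.53^2) kg), a
#' trait averaging 7.27 with wide spread, LD-blocked biallelic genotypes
#' with MAF >= 0.05, cis-acting SNP effects on expression under the additive
#' covariate-adjusted model, a designated regulator gene whose expression is
#' negatively linked to the trait, a co-expression module driven by that
#' regulator, and a small set of outlier samples carrying a global
#' expression shift (the artifact sample clustering is meant to remove).
#'
#' @param nSamples number of animals.
#' @param nSnps,nGenes genome size of the simulation.
#' @param chroms chromosome labels SNPs and genes are spread over.
#' @param snpSpacing distance between adjacent SNPs (bp).
#' @param mafRange range the per-block master allele frequency is drawn from.
#' @param plantedMafRange allele-frequency range for blocks carrying planted
#'   effects (kept at intermediate frequency, as for the strong locus in the
#'   motivating cohort).
#' @param ldBlockSize SNPs per LD block (haplotype-copy blocks).
#' @param ldWithinR within-block haplotype copy fidelity in `[0, 1]`; each
#'   haplotype allele is the block master allele flipped with probability
#'   `(1 - ldWithinR)/2`, so 1 gives identical dosages (pairwise r^2 = 1).
#' @param missingRate per-call probability of a missing genotype.
#' @param sexProportions named proportions for the sex factor.
#' @param nBatches number of slaughter batches.
#' @param weightMean,weightSd carcass weight distribution (kg).
#' @param eqtlPlan data.frame(snp, gene, beta) of planted cis pairs (ids or
#'   indices); `NULL` uses the default plan (regulator plus three cis pairs
#'   on other chromosomes).
#' @param transPlan data.frame(snp, gene, beta) of planted trans pairs
#'   (SNP on a different chromosome than the gene); `NULL` gives one pair.
#' @param covariateEffects list of per-gene effect-size SDs for sex, batch
#'   and carcass weight on latent expression.
#' @param baselineMean,baselineSd per-gene baseline latent expression
#'   (log2-FPKM scale).
#' @param noiseSd residual SD of latent expression.
#' @param modulePlan list of module specs `list(genes=, loading=, driver=)`
#'   where `driver` is `"regulator"` (module co-expresses with the regulator
#'   gene) or `NULL` (independent latent factor); `NULL` uses the default
#'   three-module plan.
#' @param regulatorGene id of the designated trait-regulating gene; `NULL`
#'   picks a gene next to the middle LD block of the first chromosome.
#' @param regulatorBeta allele-substitution effect of the regulator's causal
#'   SNP on its latent expression.
#' @param regulatorEffect signed slope of the trait on the regulator's
#'   latent (log2) expression; negative by default.
#' @param regulatorModuleLoading loading of the regulator-driven module's
#'   member genes on the standardized regulator expression.
#' @param traitMean trait intercept (IMF %% in the motivating design).
#' @param traitNoiseSd residual SD of the trait.
#' @param traitCovariateEffects list: `sex` (additive shift), `batchSd`
#'   (per-batch random intercept SD) and `weightSlope` on the trait.
#' @param nOutliers number of samples given a global expression shift.
#' @param outlierShift size of that shift (latent SD units per gene).
#' @param onMonomorphic `"regenerate"` (redraw a block whose planted SNP is
#'   monomorphic / fails MAF 0.05 or missing-rate 0.1) or `"error"`.
#' @param seed mandatory integer seed; all randomness flows from it.
#' @return A `SimulationConfig` (validated list).
#' @export
simulationConfig <- function(nSamples = 79,
                             nSnps = 400,
                             nGenes = 300,
                             chroms = c("1", "2", "3"),
                             snpSpacing = 5e4,
                             mafRange = c(0.05, 0.5),
                             plantedMafRange = c(0.25, 0.45),
                             ldBlockSize = 8,
                             ldWithinR = 0.99,
                             missingRate = 0.02,
                             sexProportions = c(male = 58, female = 21) / 79,
                             nBatches = 11,
                             weightMean = 71.20,
                             weightSd = 6.53,
                             eqtlPlan = NULL,
                             transPlan = NULL,
                             covariateEffects = list(sexSd = 0.3,
                                                     batchSd = 0.3,
                                                     weightSlopeSd = 0.01),
                             baselineMean = 3,
                             baselineSd = 0.5,
                             noiseSd = 1,
                             modulePlan = NULL,
                             regulatorGene = NULL,
                             regulatorBeta = 3,
                             regulatorEffect = -1,
                             regulatorModuleLoading = 1,
                             traitMean = 7.27,
                             traitNoiseSd = 1,
                             traitCovariateEffects = list(sex = 0.5,
                                                          batchSd = 0.3,
                                                          weightSlope = 0.05),
                             nOutliers = 9,
                             outlierShift = 3,
                             onMonomorphic = c("regenerate", "error"),
                             seed = 1) {
  if (missing(seed) && is.null(seed)) stop("a seed is mandatory")
  stopifnot(nSamples >= 2, nSnps >= 1, nGenes >= 1,
            mafRange[1] > 0, mafRange[2] <= 0.5, mafRange[1] <= mafRange[2],
            ldWithinR >= 0, ldWithinR <= 1,
            missingRate >= 0, missingRate < 1,
            noiseSd >= 0, traitNoiseSd >= 0, nOutliers >= 0)
  cfg <- list(nSamples = nSamples, nSnps = nSnps, nGenes = nGenes,
              chroms = as.character(chroms), snpSpacing = snpSpacing,
              mafRange = mafRange, plantedMafRange = plantedMafRange,
              ldBlockSize = ldBlockSize, ldWithinR = ldWithinR,
              missingRate = missingRate, sexProportions = sexProportions,
              nBatches = nBatches, weightMean = weightMean,
              weightSd = weightSd, eqtlPlan = eqtlPlan,
              transPlan = transPlan, covariateEffects = covariateEffects,
              baselineMean = baselineMean, baselineSd = baselineSd,
              noiseSd = noiseSd, modulePlan = modulePlan,
              regulatorGene = regulatorGene, regulatorBeta = regulatorBeta,
              regulatorEffect = regulatorEffect,
              regulatorModuleLoading = regulatorModuleLoading,
              traitMean = traitMean, traitNoiseSd = traitNoiseSd,
              traitCovariateEffects = traitCovariateEffects,
              nOutliers = nOutliers, outlierShift = outlierShift,
              onMonomorphic = match.arg(onMonomorphic),
              seed = as.integer(seed))
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  lay <- simulationLayout(x)
  cat(sprintf(
    "SimulationConfig: %d samples, %d SNPs (%d LD blocks), %d genes, seed %d\n",
    x$nSamples, x$nSnps, length(lay$blocks), x$nGenes, x$seed))
  cat(sprintf("  regulator: %s (beta = %g, trait slope = %g)\n",
              lay$regulatorGene, x$regulatorBeta, x$regulatorEffect))
  cat(sprintf("  planted cis pairs: %d; trans pairs: %d; modules: %d\n",
              nrow(lay$eqtlPlan), nrow(lay$transPlan), length(lay$modulePlan)))
  invisible(x)
}

#' Deterministic genome/plan layout implied by a SimulationConfig
#'
#' Resolves SNP and gene coordinates, LD block membership, the planted
#' cis/trans eQTL plans, the module plan and the regulator gene. The layout
#' is a pure function of the config (no RNG), so tests can use it as ground
#' truth.
#'
#' @param config a [simulationConfig()].
#' @return list with `snps` (id/chrom/pos/block), `genes`
#'   (id/chrom/start/end/strand/tss), `blocks` (block id -> SNP ids),
#'   `eqtlPlan`, `transPlan` (snp/gene/beta data.frames), `modulePlan`,
#'   `regulatorGene`, `outlierSamples` and `sampleIds`.
#' @export
simulationLayout <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  nc <- length(config$chroms)
  snpPerChrom <- diff(floor(config$nSnps * (0:nc) / nc))
  genePerChrom <- diff(floor(config$nGenes * (0:nc) / nc))
  snpId <- sprintf("snp%04d", seq_len(config$nSnps))
  geneId <- sprintf("gene%03d", seq_len(config$nGenes))
  snpChrom <- rep(config$chroms, snpPerChrom)
  geneChrom <- rep(config$chroms, genePerChrom)
  snpPos <- unlist(lapply(snpPerChrom, function(k)
    1e6 + seq_len(k) * config$snpSpacing), use.names = FALSE)
  snps <- data.frame(id = snpId, chrom = snpChrom, pos = snpPos,
                     stringsAsFactors = FALSE)
  # contiguous LD blocks within each chromosome
  snps$block <- unlist(lapply(split(seq_len(nrow(snps)), factor(
    snps$chrom, levels = config$chroms)), function(ix)
      paste0("c", snps$chrom[ix[1]], "b",
             ceiling(seq_along(ix) / config$ldBlockSize))), use.names = FALSE)
  blocks <- split(snps$id, factor(snps$block, levels = unique(snps$block)))
  # genes spread uniformly over each chromosome's SNP span
  tss <- unlist(mapply(function(k, nsnp) {
    span <- c(1e6, 1e6 + nsnp * config$snpSpacing)
    round(seq(span[1], span[2], length.out = k + 2)[seq_len(k) + 1])
  }, genePerChrom, snpPerChrom, SIMPLIFY = FALSE), use.names = FALSE)
  strand <- rep(c("+", "-"), length.out = config$nGenes)
  genes <- data.frame(id = geneId, chrom = geneChrom,
                      start = ifelse(strand == "+", tss, pmax(1, tss - 2e4)),
                      end = ifelse(strand == "+", tss + 2e4, tss),
                      strand = strand, tss = tss, stringsAsFactors = FALSE)

  nearestGene <- function(chrom, pos, exclude = character()) {
    cand <- genes[genes$chrom == chrom & !(genes$id %in% exclude), ]
    cand$id[which.min(abs(cand$tss - pos))]
  }
  midSnpOfBlock <- function(chrom, blockRank) {
    bl <- unique(snps$block[snps$chrom == chrom])
    members <- which(snps$block == bl[min(blockRank, length(bl))])
    snps$id[members[ceiling(length(members) / 2)]]
  }

  # regulator: gene next to the middle block of the first chromosome
  regSnp <- midSnpOfBlock(config$chroms[1],
                          ceiling(length(unique(
                            snps$block[snps$chrom == config$chroms[1]])) / 2))
  regulator <- config$regulatorGene %||%
    nearestGene(config$chroms[1], snps$pos[snps$id == regSnp])

  normalizePlan <- function(plan) {
    if (is.null(plan) || nrow(plan) == 0)
      return(data.frame(snp = character(), gene = character(),
                        beta = numeric(), stringsAsFactors = FALSE))
    plan <- as.data.frame(plan, stringsAsFactors = FALSE)
    if (is.numeric(plan$snp)) plan$snp <- snps$id[plan$snp]
    if (is.numeric(plan$gene)) plan$gene <- genes$id[plan$gene]
    stopifnot(all(plan$snp %in% snps$id), all(plan$gene %in% genes$id))
    plan
  }

  if (is.null(config$eqtlPlan)) {
    used <- regulator
    extra <- lapply(seq_len(min(3, nc * 2)), function(k) {
      chrom <- config$chroms[if (nc >= 3) (k %% (nc - 1)) + 2 else 1]
      sid <- midSnpOfBlock(chrom, 2 * k)
      gid <- nearestGene(chrom, snps$pos[snps$id == sid], exclude = used)
      used <<- c(used, gid)
      data.frame(snp = sid, gene = gid, beta = 1.2, stringsAsFactors = FALSE)
    })
    eqtlPlan <- rbind(data.frame(snp = regSnp, gene = regulator,
                                 beta = config$regulatorBeta,
                                 stringsAsFactors = FALSE),
                      do.call(rbind, extra))
    eqtlPlan <- eqtlPlan[!duplicated(eqtlPlan$gene), , drop = FALSE]
  } else {
    eqtlPlan <- normalizePlan(config$eqtlPlan)
    if (!is.null(config$regulatorGene) &&
        !(regulator %in% eqtlPlan$gene) && nrow(eqtlPlan) > 0)
      regulator <- config$regulatorGene
  }

  if (is.null(config$transPlan)) {
    transPlan <- if (nc >= 2) {
      sid <- midSnpOfBlock(config$chroms[nc], 1)
      gid <- nearestGene(config$chroms[1], 1e6,
                         exclude = c(eqtlPlan$gene, regulator))
      data.frame(snp = sid, gene = gid, beta = 1.2, stringsAsFactors = FALSE)
    } else normalizePlan(NULL)
  } else transPlan <- normalizePlan(config$transPlan)

  if (is.null(config$modulePlan)) {
    # module members are genomically dispersed: a trans-regulated regulon
    # must not sit inside the cis window of a planted locus, or its members
    # would themselves show cis signals there
    plantedSnps <- unique(c(eqtlPlan$snp, transPlan$snp))
    nearPlanted <- vapply(seq_len(nrow(genes)), function(i) {
      ps <- snps[snps$id %in% plantedSnps & snps$chrom == genes$chrom[i], ]
      nrow(ps) > 0 && any(abs(ps$pos - genes$tss[i]) <= 1.5e6)
    }, logical(1))
    pool <- setdiff(genes$id[!nearPlanted],
                    c(eqtlPlan$gene, transPlan$gene))
    take <- function(k) {
      out <- pool[seq_len(min(k, length(pool)))]
      pool <<- setdiff(pool, out)
      out
    }
    modulePlan <- list(
      mod1 = list(genes = c(regulator, take(39)), driver = "regulator",
                  loading = config$regulatorModuleLoading),
      mod2 = list(genes = take(40), driver = NULL, loading = 1),
      mod3 = list(genes = take(40), driver = NULL, loading = 1))
    modulePlan <- Filter(function(m) length(m$genes) >= 2, modulePlan)
  } else modulePlan <- config$modulePlan

  sampleIds <- sprintf("s%03d", seq_len(config$nSamples))
  outliers <- if (config$nOutliers > 0)
    utils::tail(sampleIds, config$nOutliers) else character()

  list(snps = snps, genes = genes, blocks = blocks, eqtlPlan = eqtlPlan,
       transPlan = transPlan, modulePlan = modulePlan,
       regulatorGene = regulator, sampleIds = sampleIds,
       outlierSamples = outliers)
}

# ---- genotypes -------------------------------------------------------------

#' Simulate LD-blocked biallelic genotypes
#'
#' Dosages are sums of two haplotypes. Within an LD block every SNP copies a
#' block master haplotype, flipping each allele independently with
#' probability `(1 - ldWithinR)/2`; blocks are mutually independent. Blocks
#' carrying planted effects are redrawn (or raise an error, per
#' `onMonomorphic`) until the planted SNPs are polymorphic with realized
#' MAF >= 0.05 and missing rate <= 0.1.
#'
#' @param config a [simulationConfig()].
#' @return A [GenotypeMatrix-class] (samples x SNPs).
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$nSamples < 2) stop("need at least 2 samples")
  lay <- simulationLayout(config)
  set.seed(config$seed)
  n <- config$nSamples
  f <- (1 - config$ldWithinR) / 2
  planted <- unique(c(lay$eqtlPlan$snp, lay$transPlan$snp))
  plantedBlocks <- unique(lay$snps$block[lay$snps$id %in% planted])

  drawBlock <- function(members, maf) {
    p <- stats::runif(1, maf[1], maf[2])
    master <- stats::rbinom(2 * n, 1, p)
    sapply(members, function(s) {
      flip <- if (f > 0) stats::rbinom(2 * n, 1, f) else numeric(2 * n)
      h <- abs(master - flip)
      h[seq_len(n)] + h[n + seq_len(n)]
    })
  }

  dos <- matrix(NA_real_, n, nrow(lay$snps),
                dimnames = list(lay$sampleIds, lay$snps$id))
  for (b in names(lay$blocks)) {
    members <- lay$blocks[[b]]
    maf <- if (b %in% plantedBlocks) config$plantedMafRange else
      config$mafRange
    block <- drawBlock(members, maf)
    if (config$missingRate > 0) {
      miss <- matrix(stats::rbinom(length(block), 1, config$missingRate) == 1,
                     nrow = n)
      block[miss] <- NA_real_
    }
    if (b %in% plantedBlocks) {
      plantedHere <- intersect(members, planted)
      ok <- function(bl) {
        x <- bl[, plantedHere, drop = FALSE]
        mafs <- apply(x, 2, function(v) {
          v <- v[!is.na(v)]
          af <- mean(v) / 2
          min(af, 1 - af)
        })
        missr <- colMeans(is.na(x))
        all(mafs >= 0.05) && all(missr <= 0.1)
      }
      tries <- 0
      while (!ok(block)) {
        tries <- tries + 1
        if (config$onMonomorphic == "error" || tries > 50)
          stop("planted SNP failed MAF/missingness in block ", b)
        block <- drawBlock(members, maf)
        if (config$missingRate > 0) {
          miss <- matrix(
            stats::rbinom(length(block), 1, config$missingRate) == 1,
            nrow = n)
          block[miss] <- NA_real_
        }
      }
    }
    dos[, members] <- block
  }
  GenotypeMatrix(dos, chrom = lay$snps$chrom, pos = lay$snps$pos,
                 snpIds = lay$snps$id, sampleIds = lay$sampleIds, sort = FALSE)
}

# ---- covariates ------------------------------------------------------------

#' Simulate per-sample covariates (sex, slaughter batch, carcass weight)
#'
#' @param config a [simulationConfig()].
#' @return A [SampleCovariates-class] with trait `NA` (see
#'   [simulateTrait()]).
#' @export
simulateCovariates <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  lay <- simulationLayout(config)
  set.seed(config$seed + 1L)
  n <- config$nSamples
  sex <- sample(names(config$sexProportions), n, replace = TRUE,
                prob = config$sexProportions)
  batch <- sample(sprintf("batch%02d", seq_len(config$nBatches)), n,
                  replace = TRUE)
  weight <- stats::rnorm(n, config$weightMean, config$weightSd)
  SampleCovariates(lay$sampleIds, sex, batch, weight)
}

# ---- expression ------------------------------------------------------------

#' Simulate expression with planted cis effects, covariates and modules
#'
#' Latent (log2-scale) expression of each gene is baseline + per-gene sex,
#' batch and carcass-weight effects + planted `beta * S` genetic effects +
#' module structure + Gaussian noise; outlier samples receive a global
#' shift. Values are exponentiated to an FPKM-like scale with the recorded
#' invertible transform (`latent = log2(values)`), so the rank-based
#' inverse-normal normalization downstream is invariant to the mapping.
#'
#' @param geno [GenotypeMatrix-class] from [simulateGenotypes()].
#' @param cov [SampleCovariates-class] from [simulateCovariates()].
#' @param config the same [simulationConfig()].
#' @return An [ExpressionMatrix-class] on the FPKM scale with annotation.
#' @export
simulateExpression <- function(geno, cov, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  lay <- simulationLayout(config)
  # force inputs before seeding: a lazily evaluated simulate* call in an
  # argument would otherwise reset the RNG stream mid-function
  stopifnot(identical(sampleIds(geno), lay$sampleIds),
            identical(sampleIds(cov), lay$sampleIds))
  set.seed(config$seed + 2L)
  n <- config$nSamples
  G <- config$nGenes
  dos <- apply(dosage(geno), 2, .meanImpute)

  baseline <- stats::rnorm(G, config$baselineMean, config$baselineSd)
  latent <- matrix(baseline, G, n, dimnames = list(lay$genes$id,
                                                   lay$sampleIds))
  ce <- config$covariateEffects
  sexLevels <- levels(cov@sex)
  if (length(sexLevels) >= 2 && (ce$sexSd %||% 0) > 0) {
    coefSex <- stats::rnorm(G, 0, ce$sexSd)
    ind <- as.numeric(cov@sex == sexLevels[2])
    latent <- latent + outer(coefSex, ind - mean(ind))
  }
  if (nlevels(cov@batch) >= 2 && (ce$batchSd %||% 0) > 0) {
    be <- matrix(stats::rnorm(G * nlevels(cov@batch), 0, ce$batchSd), G)
    latent <- latent + be[, as.integer(cov@batch), drop = FALSE]
  }
  if ((ce$weightSlopeSd %||% 0) > 0) {
    slope <- stats::rnorm(G, 0, ce$weightSlopeSd)
    latent <- latent + outer(slope, cov@weight - mean(cov@weight))
  }
  plan <- rbind(lay$eqtlPlan, lay$transPlan)
  for (k in seq_len(nrow(plan)))
    latent[plan$gene[k], ] <- latent[plan$gene[k], ] +
      plan$beta[k] * dos[, plan$snp[k]]
  if (config$noiseSd > 0)
    latent <- latent + matrix(stats::rnorm(G * n, 0, config$noiseSd), G, n)
  # module structure added on top of the per-gene signal
  for (m in lay$modulePlan) {
    if (identical(m$driver, "regulator")) {
      z <- latent[lay$regulatorGene, ]
      z <- (z - mean(z)) / max(stats::sd(z), .Machine$double.eps)
      members <- setdiff(m$genes, lay$regulatorGene)
    } else {
      z <- stats::rnorm(n)
      members <- m$genes
    }
    if (!length(members)) next
    latent[members, ] <- latent[members, ] +
      (m$loading %||% 1) * matrix(z, length(members), n, byrow = TRUE)
  }
  if (length(lay$outlierSamples) && config$outlierShift != 0)
    latent[, lay$outlierSamples] <- latent[, lay$outlierSamples] +
      config$outlierShift
  ExpressionMatrix(2^latent, geneInfo = lay$genes[, -1], scale = "FPKM",
                   transform = list(name = "log2"))
}

# ---- trait -----------------------------------------------------------------

#' Simulate the trait from the regulator gene and covariates
#'
#' trait = intercept + regulatorEffect * (regulator latent expression,
#' centred) + sex/batch/weight terms + Gaussian noise. With a negative
#' `regulatorEffect` the regulator is negatively correlated with the trait
#' after covariate adjustment.
#'
#' @param expr [ExpressionMatrix-class] from [simulateExpression()].
#' @param cov [SampleCovariates-class].
#' @param config the same [simulationConfig()].
#' @return `cov` with the trait slot filled.
#' @export
simulateTrait <- function(expr, cov, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  lay <- simulationLayout(config)
  if (!lay$regulatorGene %in% geneIds(expr))
    stop("regulator gene ", lay$regulatorGene, " not in expression matrix")
  reg <- latentValues(expr)[lay$regulatorGene, sampleIds(cov)]
  # the trait responds to the regulator's biological expression: remove the
  # technical outlier shift, which is a measurement artifact, before use
  shifted <- intersect(lay$outlierSamples, sampleIds(cov))
  reg[shifted] <- reg[shifted] - config$outlierShift
  set.seed(config$seed + 3L)
  n <- length(sampleIds(cov))
  te <- config$traitCovariateEffects
  trait <- config$traitMean + config$regulatorEffect * (reg - mean(reg))
  sexLevels <- levels(cov@sex)
  if (length(sexLevels) >= 2 && (te$sex %||% 0) != 0) {
    ind <- as.numeric(cov@sex == sexLevels[2])
    trait <- trait + te$sex * (ind - mean(ind))
  }
  if ((te$batchSd %||% 0) > 0) {
    be <- stats::rnorm(nlevels(cov@batch), 0, te$batchSd)
    eff <- be[as.integer(cov@batch)]
    trait <- trait + eff - mean(eff)
  }
  if ((te$weightSlope %||% 0) != 0)
    trait <- trait + te$weightSlope * (cov@weight - mean(cov@weight))
  if (config$traitNoiseSd > 0)
    trait <- trait + stats::rnorm(n, 0, config$traitNoiseSd)
  SampleCovariates(sampleIds(cov), cov@sex, cov@batch, cov@weight, trait)
}

# ---- dataset on disk -------------------------------------------------------

#' Write a complete synthetic dataset to disk
#'
#' Produces `genotypes.vcf`, `expression.tsv`, `annotation.tsv`,
#' `covariates.tsv`, a `gwas.tsv` summary obtained by running the single-SNP
#' trait scan ([gwasScan()]) on the QC-passed simulated genotypes, and a
#' `truth.json` ground-truth file (planted pairs with realized MAF, the
#' regulator, module plan, LD blocks, outliers).
#'
#' @param config a [simulationConfig()].
#' @param outdir writable output directory (created if absent).
#' @return Invisibly, a list with the file `paths` and the in-memory
#'   objects (`genotypes`, `expression`, `covariates`, `gwas`, `truth`).
#' @export
makeDataset <- function(config, outdir) {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lay <- simulationLayout(config)
  geno <- simulateGenotypes(config)
  cov <- simulateCovariates(config)
  expr <- simulateExpression(geno, cov, config)
  cov <- simulateTrait(expr, cov, config)
  qc <- qcGenotypes(geno)
  gwas <- gwasScan(qc$genotypes, cov)
  paths <- file.path(outdir, c(genotypes = "genotypes.vcf",
                               expression = "expression.tsv",
                               annotation = "annotation.tsv",
                               covariates = "covariates.tsv",
                               gwas = "gwas.tsv",
                               truth = "truth.json"))
  names(paths) <- c("genotypes", "expression", "annotation", "covariates",
                    "gwas", "truth")
  writeGenotypes(geno, paths["genotypes"])
  writeExpression(expr, paths["expression"], paths["annotation"])
  writeCovariates(cov, paths["covariates"])
  writeGwas(gwas, paths["gwas"])
  d <- dosage(geno)
  realizedMaf <- vapply(lay$eqtlPlan$snp, function(s) {
    v <- d[, s]; v <- v[!is.na(v)]
    af <- mean(v) / 2
    min(af, 1 - af)
  }, numeric(1))
  truth <- list(
    schema = "imfscan-truth/1",
    seed = config$seed,
    eqtl_plan = cbind(lay$eqtlPlan, realized_maf = realizedMaf,
                      retained = realizedMaf >= 0.05),
    trans_plan = lay$transPlan,
    regulator = list(gene = lay$regulatorGene,
                     effect = config$regulatorEffect,
                     beta = config$regulatorBeta),
    modules = lapply(lay$modulePlan, function(m)
      list(genes = m$genes, driver = m$driver %||% "latent",
           loading = m$loading %||% 1)),
    ld_blocks = lapply(lay$blocks, identity),
    outlier_samples = lay$outlierSamples)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(list(paths = as.list(paths), genotypes = geno, expression = expr,
                 covariates = cov, gwas = gwas, truth = truth))
}
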