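#' @include methods.R
NULL

#' Genotype quality control
#'
#' Individuals with a missing rate above `indMissMax` are removed first;
#' then, on the retained individuals, SNPs are removed if their minor allele
#' frequency (computed from non-missing dosages) is below `mafMin`, their
#' missing rate exceeds `snpMissMax`, or they lie on mitochondria or
#' scaffold contigs. All comparisons are strict, so boundary values (MAF
#' exactly 0.05, missing rate exactly 0.1) are retained.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param mafMin exclude SNPs with MAF strictly below this (default 0.05).
#' @param snpMissMax exclude SNPs with missing rate strictly above this
#'   (default 0.1).
#' @param indMissMax exclude individuals with missing rate strictly above
#'   this (default 0.1).
#' @param dropNonchrom drop SNPs on mitochondrial/scaffold contigs?
#' @return list with `genotypes` (filtered [GenotypeMatrix-class]) and
#'   `report` (per-filter removal counts).
#' @export
qcGenotypes <- function(geno, mafMin = 0.05, snpMissMax = 0.1,
                        indMissMax = 0.1, dropNonchrom = TRUE) {
  d <- dosage(geno)
  info <- snpInfo(geno)
  indMiss <- rowMeans(is.na(d))
  keepInd <- indMiss <= indMissMax
  if (!any(keepInd)) stop("all individuals removed by missing-rate filter")
  d2 <- d[keepInd, , drop = FALSE]

  nonchrom <- if (dropNonchrom)
    grepl("scaf|contig", info$chrom, ignore.case = TRUE) |
      toupper(info$chrom) %in% c("MT", "M", "CHRM", "CHRMT")
  else rep(FALSE, ncol(d2))
  snpMiss <- colMeans(is.na(d2))
  af <- colMeans(d2, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  failMiss <- !nonchrom & snpMiss > snpMissMax
  failMaf <- !nonchrom & !failMiss & maf < mafMin
  keepSnp <- !(nonchrom | failMiss | failMaf)

  out <- geno[which(keepInd), which(keepSnp)]
  report <- list(n_samples_in = nrow(d), n_samples_out = sum(keepInd),
                 n_snps_in = ncol(d), n_snps_out = sum(keepSnp),
                 removed = c(individual_missing = sum(!keepInd),
                             nonchromosomal = sum(nonchrom),
                             snp_missing = sum(failMiss),
                             maf = sum(failMaf)))
  list(genotypes = out, report = report)
}

#' Fit one SNP-expression (or SNP-trait) association
#'
#' Ordinary least squares of the response on intercept + dosage + carcass
#' weight + sex and batch dummies: `g = beta * S + bw + se + ba + e`. The
#' t statistic is `beta_hat / SE` on residual degrees of freedom; the
#' p-value is two-sided. Missing dosages are mean-imputed by default
#' (`missing = "complete"` drops those samples instead). Rank-deficient
#' designs (e.g. a batch confounded with the SNP) drop the offending dummy
#' columns with a warning; a constant dosage yields `NULL` with a message.
#'
#' @param g numeric response vector (normalized expression or trait), named
#'   by sample id or aligned with `S`.
#' @param S dosage vector for one SNP.
#' @param cov a [SampleCovariates-class] aligned with `g`.
#' @param missing `"impute"` (per-SNP mean) or `"complete"` (drop samples).
#' @param minSamples minimum complete samples (default 10).
#' @return one-row data.frame: beta, se, t, p, n_used — or `NULL` when the
#'   dosage is constant.
#' @export
fitAssociation <- function(g, S, cov, missing = c("impute", "complete"),
                           minSamples = 10) {
  missing <- match.arg(missing)
  stopifnot(length(g) == length(S), length(g) == length(sampleIds(cov)))
  keep <- !is.na(g)
  if (missing == "impute") S <- .meanImpute(S) else keep <- keep & !is.na(S)
  keep <- keep & !is.na(S)
  if (sum(keep) < minSamples)
    stop("fewer than ", minSamples, " samples with complete data")
  g <- g[keep]
  S <- S[keep]
  covK <- cov[which(keep)]
  if (stats::var(S) == 0) {
    message("constant dosage after QC; association skipped")
    return(NULL)
  }
  X <- cbind(.covariateDesign(covK), S = S)
  fit <- .olsFit(X, g)
  if (fit$rank < ncol(X)) {
    dropped <- colnames(X)[is.na(fit$coef)]
    if ("S" %in% dropped) {
      message("dosage aliased with covariates; association skipped")
      return(NULL)
    }
    warning("rank-deficient design; dropped: ",
            paste(dropped, collapse = ", "))
  }
  beta <- unname(fit$coef["S"])
  se <- unname(fit$se["S"])
  tstat <- beta / se
  data.frame(beta = beta, se = se, t = tstat,
             p = 2 * stats::pt(-abs(tstat), df = fit$df),
             n_used = length(g))
}

#' Classify SNP-gene pairs as cis or trans
#'
#' A pair is cis iff SNP and transcription start site share a chromosome and
#' `|pos - tss| <= window` (boundary inclusive; set `inclusive = FALSE` for
#' a strict window).
#'
#' @param snpChrom,snpPos SNP coordinates (vectors recycle).
#' @param tssChrom,tssPos gene TSS coordinates.
#' @param window cis window in bp (default 1 Mb).
#' @param inclusive include the window boundary? Default `TRUE`.
#' @return character vector of `"cis"` / `"trans"`.
#' @export
classifyRelation <- function(snpChrom, snpPos, tssChrom, tssPos,
                             window = 1e6, inclusive = TRUE) {
  d <- abs(snpPos - tssPos)
  inWin <- if (inclusive) d <= window else d < window
  ifelse(snpChrom == tssChrom & inWin, "cis", "trans")
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values (monotone in p, capped at 1).
#' @export
bhFdr <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Scan SNP-gene pairs for eQTLs
#'
#' Fits [fitAssociation()] for every pair in scope — by default only cis
#' pairs (SNP within `window` of the gene TSS) — flags each record at the
#' genome-wide (`p < pGenomewide`) and suggestive (`p < pSuggestive`)
#' thresholds (strict comparisons), and computes Benjamini-Hochberg q-values
#' over all fitted pairs as one family.
#'
#' @param expr normalized [ExpressionMatrix-class] with gene annotation.
#' @param geno QC-passed [GenotypeMatrix-class].
#' @param cov [SampleCovariates-class].
#' @param mode `"cis_only"` (default) or `"all"` (every pair, quadratic).
#' @param window cis window (bp).
#' @param pGenomewide,pSuggestive significance thresholds.
#' @param missing passed to [fitAssociation()].
#' @return data.frame of association records (snp_id, gene_id, coordinates,
#'   beta, se, t, p, q, relation, significance flags, n_used).
#' @export
eqtlScan <- function(expr, geno, cov, mode = c("cis_only", "all"),
                     window = 1e6, pGenomewide = 5e-8, pSuggestive = 5e-6,
                     missing = "impute") {
  mode <- match.arg(mode)
  if (nrow(exprValues(expr)) == 0) stop("empty expression matrix")
  ginfo <- geneInfo(expr)
  if (!ncol(ginfo)) stop("expression matrix has no gene annotation (TSS)")
  samples <- .alignSamples(sampleIds(expr), sampleIds(geno), sampleIds(cov))
  v <- exprValues(expr)[, samples, drop = FALSE]
  d <- dosage(geno)[samples, , drop = FALSE]
  covA <- cov[samples]
  sinfo <- snpInfo(geno)

  if (mode == "cis_only") {
    snpGr <- GenomicRanges::GRanges(sinfo$chrom,
                                    IRanges::IRanges(sinfo$pos, sinfo$pos))
    tssGr <- GenomicRanges::GRanges(
      ginfo$chrom,
      IRanges::IRanges(pmax(1, ginfo$tss - window), ginfo$tss + window))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(tssGr, snpGr))
    pairs <- data.frame(gene = S4Vectors::queryHits(hits),
                        snp = S4Vectors::subjectHits(hits))
  } else {
    pairs <- expand.grid(gene = seq_len(nrow(v)), snp = seq_len(ncol(d)))
  }
  if (nrow(pairs) == 0) {
    warning("no ", if (mode == "cis_only") "cis " else "", "pairs to test")
    return(.emptyScan())
  }

  recs <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    gi <- pairs$gene[k]
    si <- pairs$snp[k]
    r <- suppressMessages(
      fitAssociation(v[gi, ], d[, si], covA, missing = missing))
    if (is.null(r)) next
    recs[[k]] <- data.frame(
      snp_id = colnames(d)[si], gene_id = rownames(v)[gi],
      chrom_snp = sinfo$chrom[si], pos_snp = sinfo$pos[si],
      chrom_gene = ginfo$chrom[gi], tss = ginfo$tss[gi], r,
      stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) {
    warning("no testable pairs (all dosages constant)")
    return(.emptyScan())
  }
  out <- do.call(rbind, recs)
  out$q <- bhFdr(out$p)
  out$relation <- classifyRelation(out$chrom_snp, out$pos_snp,
                                   out$chrom_gene, out$tss, window = window)
  out$significant_gw <- out$p < pGenomewide
  out$significant_sugg <- out$p < pSuggestive
  rownames(out) <- NULL
  out
}

.emptyScan <- function() {
  data.frame(snp_id = character(), gene_id = character(),
             chrom_snp = character(), pos_snp = numeric(),
             chrom_gene = character(), tss = numeric(), beta = numeric(),
             se = numeric(), t = numeric(), p = numeric(),
             n_used = integer(), q = numeric(), relation = character(),
             significant_gw = logical(), significant_sugg = logical(),
             stringsAsFactors = FALSE)
}
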