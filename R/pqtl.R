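#' @include eqtl.R
NULL

#' Single-SNP trait association scan (GWAS-style)
#'
#' Reuses the additive covariate-adjusted linear model with the trait as
#' response: per SNP, `trait ~ S + weight + sex + batch`, two-sided p.
#'
#' @param geno QC-passed [GenotypeMatrix-class].
#' @param cov [SampleCovariates-class] with the trait filled.
#' @param missing passed to [fitAssociation()].
#' @return A [GwasSummary-class] whose table also carries snp_id, beta, se
#'   and t columns.
#' @export
gwasScan <- function(geno, cov, missing = "impute") {
  y <- traitValues(cov)
  if (all(is.na(y))) stop("covariates carry no trait")
  samples <- .alignSamples(sampleIds(geno), sampleIds(cov)[!is.na(y)])
  d <- dosage(geno)[samples, , drop = FALSE]
  covA <- cov[samples]
  y <- traitValues(covA)
  if (stats::var(y) == 0) stop("constant trait")
  info <- snpInfo(geno)
  recs <- lapply(seq_len(ncol(d)), function(j) {
    r <- suppressMessages(fitAssociation(y, d[, j], covA, missing = missing))
    if (is.null(r)) return(NULL)
    data.frame(snp_id = colnames(d)[j], chrom = info$chrom[j],
               pos = info$pos[j], beta = r$beta, se = r$se, t = r$t,
               p = r$p, stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(recs)) stop("no testable SNPs")
  out <- GwasSummary(recs$chrom, recs$pos, recs$p, snpId = recs$snp_id)
  o <- match(paste(out@table$chrom, out@table$pos),
             paste(recs$chrom, recs$pos))
  out@table$beta <- recs$beta[o]
  out@table$se <- recs$se[o]
  out@table$t <- recs$t[o]
  out
}

#' 2-LOD drop support interval
#'
#' One unit of -log10(p) is taken as one LOD unit. All SNPs on the chosen
#' chromosome with LOD strictly above (peak LOD - `drop`) are retained; the
#' interval spans the maximal contiguous retained run containing the peak
#' (`spanAll = TRUE` spans every retained SNP on the chromosome instead).
#'
#' @param gwas a [GwasSummary-class].
#' @param chrom chromosome to profile; default = chromosome of the global
#'   peak.
#' @param drop LOD drop (default 2).
#' @param spanAll span all retained SNPs rather than the peak's run?
#' @return A length-one [GenomicRanges::GRanges] with metadata columns
#'   `peak_pos`, `peak_lod`, `n_retained`.
#' @export
lodDropInterval <- function(gwas, chrom = NULL, drop = 2, spanAll = FALSE) {
  tab <- gwasTable(gwas)
  if (nrow(tab) == 0) stop("empty GWAS summary")
  lod <- -log10(tab$p)
  chrom <- chrom %||% tab$chrom[which.max(lod)]
  sel <- tab$chrom == chrom
  if (!any(sel)) stop("no SNPs on chromosome ", chrom)
  pos <- tab$pos[sel]
  lodc <- lod[sel]
  peak <- which.max(lodc)
  retained <- lodc > lodc[peak] - drop
  if (spanAll) {
    lo <- min(pos[retained])
    hi <- max(pos[retained])
  } else {
    runs <- rle(retained)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    k <- which(runs$values & starts <= peak & ends >= peak)
    lo <- pos[starts[k]]
    hi <- pos[ends[k]]
  }
  iv <- genomicInterval(chrom, lo, hi, label = "pQTL")
  S4Vectors::mcols(iv)$peak_pos <- pos[peak]
  S4Vectors::mcols(iv)$peak_lod <- lodc[peak]
  S4Vectors::mcols(iv)$n_retained <- sum(retained)
  iv
}

#' Pairwise LD as squared dosage correlation
#'
#' Composite LD: the squared Pearson correlation of the two dosage vectors
#' over pairwise-complete samples.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param i,j SNP indices or ids.
#' @return r-squared in `[0, 1]`, or `NA` (with a warning) if either SNP is
#'   monomorphic on the shared samples.
#' @export
ldR2 <- function(geno, i, j) {
  d <- dosage(geno)
  x <- d[, i]
  y <- d[, j]
  ok <- !is.na(x) & !is.na(y)
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
    warning("monomorphic SNP; r-squared undefined")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])^2
}

#' Find contiguous LD blocks (all pairwise r-squared above a threshold)
#'
#' Greedy left-to-right extension in map order: a SNP joins the current
#' block iff its r-squared with every current member exceeds `r2Min`;
#' otherwise the block is closed (reported when it has >= 2 members) and a
#' new one starts. Monomorphic SNPs are excluded with a warning.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param chrom restrict to one chromosome (default: all, per chromosome).
#' @param region optional [GenomicRanges::GRanges] restricting positions.
#' @param r2Min threshold (default 0.90, strict >).
#' @return data.frame with one row per block: chrom, start_pos, end_pos,
#'   n_snps, min_r2 and a list column `snps` of member ids.
#' @export
findLdBlocks <- function(geno, chrom = NULL, region = NULL, r2Min = 0.90) {
  info <- snpInfo(geno)
  sel <- rep(TRUE, nrow(info))
  if (!is.null(chrom)) sel <- sel & info$chrom %in% chrom
  if (!is.null(region)) {
    rc <- as.character(GenomicRanges::seqnames(region))[1]
    sel <- sel & info$chrom == rc &
      info$pos >= GenomicRanges::start(region)[1] &
      info$pos <= GenomicRanges::end(region)[1]
  }
  idx <- which(sel)
  d <- dosage(geno)
  mono <- vapply(idx, function(j)
    stats::var(d[, j], na.rm = TRUE) == 0, logical(1))
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) excluded from block finding")
    idx <- idx[!mono]
  }
  out <- list()
  for (ch in unique(info$chrom[idx])) {
    ix <- idx[info$chrom[idx] == ch]
    if (!length(ix)) next
    members <- ix[1]
    r2s <- numeric()
    flush <- function() {
      if (length(members) >= 2)
        out[[length(out) + 1]] <<- data.frame(
          chrom = ch, start_pos = info$pos[members[1]],
          end_pos = info$pos[members[length(members)]],
          n_snps = length(members), min_r2 = min(r2s),
          snps = I(list(rownames(info)[members])),
          stringsAsFactors = FALSE)
    }
    for (j in ix[-1]) {
      r2 <- vapply(members, function(m) ldR2(geno, m, j), numeric(1))
      if (all(r2 > r2Min)) {
        members <- c(members, j)
        r2s <- c(r2s, r2)
      } else {
        flush()
        members <- j
        r2s <- numeric()
      }
    }
    flush()
  }
  if (!length(out))
    return(data.frame(chrom = character(), start_pos = numeric(),
                      end_pos = numeric(), n_snps = integer(),
                      min_r2 = numeric(), snps = I(list())))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Colocalize a pQTL interval with significant cis-eQTLs
#'
#' For each gene, counts the significant cis-eQTLs whose SNP lies within the
#' pQTL interval (inclusive ends), and reports the gene's spanning eQTL
#' region and its overlap with the interval.
#'
#' @param pqtl length-one [GenomicRanges::GRanges] (from
#'   [lodDropInterval()]).
#' @param eqtlRecords data.frame from [eqtlScan()].
#' @param flag which significance flag defines "significant" (default the
#'   suggestive threshold, as in the motivating analysis).
#' @return data.frame per gene: n_coloc (SNPs inside the interval), ids of
#'   those SNPs (list column), the gene's eQTL span and its overlap (bp)
#'   with the pQTL; sorted by n_coloc descending. Zero rows when nothing
#'   overlaps.
#' @export
colocalize <- function(pqtl, eqtlRecords,
                       flag = c("significant_sugg", "significant_gw")) {
  flag <- match.arg(flag)
  sig <- eqtlRecords[eqtlRecords[[flag]] & eqtlRecords$relation == "cis", ,
                     drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(gene_id = character(), n_coloc = integer(),
                      n_significant = integer(), span_start = numeric(),
                      span_end = numeric(), overlap_bp = numeric(),
                      snps = I(list())))
  chrom <- as.character(GenomicRanges::seqnames(pqtl))[1]
  lo <- GenomicRanges::start(pqtl)[1]
  hi <- GenomicRanges::end(pqtl)[1]
  res <- lapply(split(sig, sig$gene_id), function(tab) {
    inside <- tab$chrom_snp == chrom & tab$pos_snp >= lo & tab$pos_snp <= hi
    span <- suppressWarnings(range(tab$pos_snp[tab$chrom_snp == chrom]))
    ov <- if (any(tab$chrom_snp == chrom))
      max(0, min(hi, span[2]) - max(lo, span[1]) + 1) else 0
    data.frame(gene_id = tab$gene_id[1], n_coloc = sum(inside),
               n_significant = nrow(tab),
               span_start = if (is.finite(span[1])) span[1] else NA_real_,
               span_end = if (is.finite(span[2])) span[2] else NA_real_,
               overlap_bp = ov,
               snps = I(list(tab$snp_id[inside])), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[out$n_coloc > 0, , drop = FALSE]
  out <- out[order(-out$n_coloc, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutation association of selected SNPs with the trait
#'
#' The observed statistic per SNP is |t| from the covariate-adjusted model
#' (equivalently, the partial correlation of trait and dosage given the
#' covariates). Covariate-adjusted trait residuals are permuted
#' (Freedman-Lane style), giving pointwise add-one empirical p-values
#' `p = (1 + #{perm >= obs}) / (nPerm + 1)` and family-wise max-T p-values
#' using each permutation's maximum over the SNP set.
#'
#' @param geno [GenotypeMatrix-class] restricted to the SNPs of interest, or
#'   a dosage matrix (samples x SNPs).
#' @param cov [SampleCovariates-class] with the trait filled.
#' @param nPerm number of permutations (default 100000).
#' @param seed RNG seed for the permutations.
#' @return data.frame: snp_id, t_obs, p_pointwise, p_familywise.
#' @export
permutationAssoc <- function(geno, cov, nPerm = 1e5, seed = 1) {
  stopifnot(nPerm >= 1)
  d <- if (is(geno, "GenotypeMatrix")) dosage(geno) else as.matrix(geno)
  samples <- .alignSamples(rownames(d), sampleIds(cov))
  d <- d[samples, , drop = FALSE]
  covA <- cov[samples]
  y <- traitValues(covA)
  n <- length(y)
  X <- .covariateDesign(covA)
  qrX <- qr(X)
  rankCov <- qrX$rank
  df <- n - rankCov - 1
  ey <- qr.resid(qrX, y)
  eS <- apply(d, 2, function(s) qr.resid(qrX, .meanImpute(s)))
  norm1 <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv == 0) rep(0, length(v)) else v / nv
  }
  eyn <- norm1(ey)
  eSn <- apply(eS, 2, norm1)
  rObs <- abs(drop(crossprod(eSn, eyn)))
  m <- ncol(d)
  set.seed(seed)
  countGe <- numeric(m)
  countMax <- numeric(m)
  chunk <- 10000L
  done <- 0L
  while (done < nPerm) {
    b <- min(chunk, nPerm - done)
    P <- matrix(0, n, b)
    for (k in seq_len(b)) P[, k] <- eyn[sample.int(n)]
    rPerm <- abs(crossprod(eSn, P))          # m x b
    countGe <- countGe + rowSums(rPerm >= rObs)
    mx <- apply(rPerm, 2, max)
    countMax <- countMax + vapply(rObs, function(o) sum(mx >= o), numeric(1))
    done <- done + b
  }
  tObs <- rObs * sqrt(df) / sqrt(pmax(1 - rObs^2, .Machine$double.eps))
  data.frame(snp_id = colnames(d), t_obs = tObs,
             p_pointwise = (1 + countGe) / (nPerm + 1),
             p_familywise = (1 + countMax) / (nPerm + 1),
             stringsAsFactors = FALSE)
}

#' Raw trait summary by genotype class at one SNP
#'
#' Reports unadjusted trait mean and SE (sd/sqrt(n)) per genotype class and
#' an unpaired two-tailed Student's t-test between the two largest classes.
#' Singleton classes are reported mean-only.
#'
#' @param S dosage vector for one SNP (0/1/2, NA allowed).
#' @param trait trait vector aligned with `S`.
#' @return list with `stats` (per-class n, mean, se) and `test` (the two
#'   compared classes and the t-test p-value).
#' @export
genotypeStratifiedTest <- function(S, trait) {
  ok <- !is.na(S) & !is.na(trait)
  S <- S[ok]
  trait <- trait[ok]
  cls <- factor(S, levels = sort(unique(S)))
  stats <- do.call(rbind, lapply(levels(cls), function(l) {
    v <- trait[cls == l]
    data.frame(genotype = l, n = length(v), mean = mean(v),
               se = if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
               else NA_real_, stringsAsFactors = FALSE)
  }))
  usable <- stats$genotype[stats$n >= 2]
  if (length(usable) < 2)
    stop("need at least two genotype classes with >= 2 members")
  big <- stats[stats$n >= 2, , drop = FALSE]
  topTwo <- big$genotype[order(-big$n, big$genotype)][1:2]
  tt <- stats::t.test(trait[cls == topTwo[1]], trait[cls == topTwo[2]],
                      var.equal = TRUE)
  list(stats = stats,
       test = list(groups = topTwo, p = tt$p.value,
                   t = unname(tt$statistic)))
}
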