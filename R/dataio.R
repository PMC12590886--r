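#' @include methods.R
NULL

# ---- genotypes (VCF) -------------------------------------------------------

#' Read genotype dosages from a VCF file
#'
#' Only biallelic records with a GT field are used; multiallelic records are
#' skipped with a warning. Dosage is the count of alternative alleles
#' (0/1/2); missing calls (`./.`) become `NA`.
#'
#' @param path path to a VCF (plain text or bgzip).
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("malformed VCF '", path, "': ", conditionMessage(e)))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) stop("no variant records in ", path)
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi))
    warning(sum(!bi), " multiallelic record(s) skipped in ", path)
  if (!any(bi)) stop("no biallelic records in ", path)
  vcf <- vcf[bi, ]
  fix <- vcf@fix
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  dos <- .gtToDosage(gt)              # variants x samples
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "." | ids == ""
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  GenotypeMatrix(t(dos), chrom = fix[, "CHROM"],
                 pos = as.numeric(fix[, "POS"]),
                 snpIds = make.unique(ids), sampleIds = colnames(gt))
}

# "0/0" -> 0, "0/1" -> 1, "1|1" -> 2, "./." or "." -> NA
.gtToDosage <- function(gt) {
  parse1 <- function(s) {
    if (is.na(s) || s == "." || s == "./." || s == ".|.") return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  }
  u <- unique(as.vector(gt))
  map <- vapply(u, parse1, numeric(1))
  out <- matrix(map[match(gt, u)], nrow = nrow(gt), dimnames = dimnames(gt))
  out
}

#' Write a GenotypeMatrix to a minimal GT-only VCF
#'
#' Emits a VCFv4.2 file with placeholder REF/ALT alleles (A/G) and a single
#' GT FORMAT field, sufficient to round-trip dosages through
#' [readGenotypes()].
#'
#' @param geno a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(geno, path) {
  d <- dosage(geno)
  info <- snpInfo(geno)
  gtmap <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##source=imfscan",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             sprintf("##contig=<ID=%s>", unique(info$chrom)),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  ok <- !is.na(t(d))
  gt[ok] <- gtmap[t(d)[ok] + 1]
  body <- paste(info$chrom, format(info$pos, scientific = FALSE, trim = TRUE),
                colnames(d), "A", "G", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

# ---- expression (TSV) ------------------------------------------------------

#' Read an expression matrix (genes x samples TSV)
#'
#' The first column holds gene identifiers; the header row holds sample
#' identifiers. An optional annotation TSV (`gene_id`, `chrom`, `start`,
#' `end`, `strand`) supplies coordinates; genes absent from the annotation
#' are dropped with a warning.
#'
#' @param path expression TSV path.
#' @param annotationPath optional annotation TSV path.
#' @param scale abundance scale tag of the stored values.
#' @return An [ExpressionMatrix-class].
#' @export
readExpression <- function(path, annotationPath = NULL, scale = "FPKM") {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression TSV needs gene id + sample columns")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                   ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
    storage.mode(m) <- "double"
  }
  rownames(m) <- ids
  info <- NULL
  if (!is.null(annotationPath)) {
    ann <- utils::read.delim(annotationPath, header = TRUE,
                             stringsAsFactors = FALSE)
    rownames(ann) <- ann$gene_id
    keep <- ids %in% ann$gene_id
    if (any(!keep))
      warning(sum(!keep), " gene(s) absent from annotation dropped")
    m <- m[keep, , drop = FALSE]
    info <- ann[rownames(m), c("chrom", "start", "end", "strand"),
                drop = FALSE]
    info$chrom <- as.character(info$chrom)
  }
  ExpressionMatrix(m, geneInfo = info, scale = scale)
}

#' Write an ExpressionMatrix (and optionally its annotation) to TSV
#'
#' @param expr an [ExpressionMatrix-class].
#' @param path output TSV path.
#' @param annotationPath optional path for the gene annotation TSV.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path, annotationPath = NULL) {
  v <- exprValues(expr)
  out <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotationPath)) {
    info <- as.data.frame(geneInfo(expr))
    if (!ncol(info)) stop("no gene annotation to write")
    ann <- data.frame(gene_id = rownames(info),
                      info[, c("chrom", "start", "end", "strand")],
                      stringsAsFactors = FALSE)
    utils::write.table(ann, annotationPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# ---- covariates ------------------------------------------------------------

#' Read per-sample covariates (sample_id, sex, batch, weight[, trait])
#'
#' @param path covariate TSV path.
#' @return A [SampleCovariates-class].
#' @export
readCovariates <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "batch", "weight")
  if (!all(need %in% colnames(tab)))
    stop("covariate TSV needs columns: ", paste(need, collapse = ", "))
  SampleCovariates(tab$sample_id, tab$sex, tab$batch, tab$weight,
                   trait = if ("trait" %in% colnames(tab)) tab$trait else
                     rep(NA_real_, nrow(tab)))
}

#' Write SampleCovariates to TSV
#'
#' @param cov a [SampleCovariates-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCovariates <- function(cov, path) {
  utils::write.table(covariateTable(cov), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- GWAS summary ----------------------------------------------------------

#' Read GWAS summary statistics (chrom, pos, p TSV)
#'
#' p-values outside (0, 1] are rejected; duplicate (chrom, pos) rows keep the
#' first record with a warning.
#'
#' @param path summary TSV path.
#' @return A [GwasSummary-class].
#' @export
readGwas <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "p") %in% colnames(tab)))
    stop("GWAS TSV needs chrom/pos/p columns")
  if (any(tab$p <= 0 | tab$p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  key <- paste(tab$chrom, tab$pos)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate (chrom, pos) record(s) dropped")
    tab <- tab[!duplicated(key), , drop = FALSE]
  }
  GwasSummary(tab$chrom, tab$pos, tab$p,
              snpId = if ("snp_id" %in% colnames(tab)) tab$snp_id else NULL)
}

#' Write a GwasSummary to TSV
#'
#' @param gwas a [GwasSummary-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeGwas <- function(gwas, path) {
  utils::write.table(gwasTable(gwas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- genomic intervals -----------------------------------------------------

#' Build a labelled 1-based inclusive genomic interval
#'
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive bounds (start <= end).
#' @param label interval name.
#' @return A length-one [GenomicRanges::GRanges].
#' @export
genomicInterval <- function(chrom, start, end, label = "interval") {
  stopifnot(start <= end, start >= 1)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  names(gr) <- label
  gr
}

#' Write intervals to a BED file
#'
#' Internal coordinates are 1-based inclusive; BED uses 0-based half-open,
#' so starts are shifted down by one.
#'
#' @param intervals a [GenomicRanges::GRanges] (named ranges become the BED
#'   name column).
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
writeIntervals <- function(intervals, path) {
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(intervals)),
    start = GenomicRanges::start(intervals) - 1L,
    end = GenomicRanges::end(intervals),
    name = names(intervals) %||% paste0("iv", seq_along(intervals)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
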