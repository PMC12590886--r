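#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.DOSAGE_LEVELS <- c(0, 1, 2)

#' GenotypeMatrix: samples x SNPs dosage matrix with variant metadata
#'
#' Dosages count copies of the alternative allele (0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternative); missing calls are `NA`.
#' Variant metadata (`chrom`, `pos`) is carried in a parallel
#' [S4Vectors::DataFrame] keyed by SNP id, sorted by position within each
#' chromosome.
#'
#' @slot dosage numeric matrix, samples in rows, SNPs in columns, values in
#'   \{0, 1, 2, NA\}; dimnames give sample and SNP identifiers.
#' @slot snpInfo `DataFrame` with one row per SNP and columns `chrom`
#'   (character) and `pos` (1-based bp position).
#' @export
setClass("GenotypeMatrix",
         slots = c(dosage = "matrix", snpInfo = "DataFrame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  info <- object@snpInfo
  msgs <- character()
  if ((nrow(d) > 0 && is.null(rownames(d))) ||
      (ncol(d) > 0 && is.null(colnames(d))))
    msgs <- c(msgs, "dosage must carry sample (row) and SNP (column) names")
  if (ncol(d) != nrow(info))
    msgs <- c(msgs, "snpInfo must have one row per dosage column")
  if (ncol(d) > 0 && !identical(colnames(d), rownames(info)))
    msgs <- c(msgs, "snpInfo rownames must match dosage column names")
  if (anyDuplicated(colnames(d)))
    msgs <- c(msgs, "SNP ids must be unique")
  if (anyDuplicated(rownames(d)))
    msgs <- c(msgs, "sample ids must be unique")
  if (!all(c("chrom", "pos") %in% colnames(info)))
    msgs <- c(msgs, "snpInfo needs 'chrom' and 'pos' columns")
  else {
    if (any(info$pos < 1, na.rm = TRUE))
      msgs <- c(msgs, "positions must be >= 1")
    if (is.unsorted(order(factor(info$chrom, levels = unique(info$chrom)),
                          info$pos), strictly = FALSE) ||
        any(tapply(info$pos, factor(info$chrom, levels = unique(info$chrom)),
                   is.unsorted)))
      msgs <- c(msgs, "SNPs must be position-sorted within each chromosome")
  }
  vals <- d[!is.na(d)]
  if (length(vals) && !all(vals %in% .DOSAGE_LEVELS))
    msgs <- c(msgs, "dosage values must be 0, 1, 2 or NA")
  if (length(msgs)) msgs else TRUE
})

#' ExpressionMatrix: genes x samples abundance matrix with gene annotation
#'
#' Holds abundances on a declared scale (`"counts"`, `"FPKM"`, `"TPM"` or
#' `"normalized"` after rank-based inverse-normal transformation) together
#' with per-gene coordinates. The transcription start site (`tss`) is the
#' gene start on the `+` strand and the gene end on the `-` strand.
#'
#' @slot values numeric matrix, genes in rows, samples in columns.
#' @slot geneInfo `DataFrame` with columns `chrom`, `start`, `end`, `strand`,
#'   `tss` (all 1-based); may have zero columns when annotation is absent.
#' @slot scale single string naming the abundance scale.
#' @slot transform list recording an invertible map back to a latent linear
#'   scale (used by the synthetic generator), e.g. `list(name = "log2")`
#'   meaning latent = log2(values); empty when not applicable.
#' @export
setClass("ExpressionMatrix",
         slots = c(values = "matrix", geneInfo = "DataFrame",
                   scale = "character", transform = "list"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  info <- object@geneInfo
  msgs <- character()
  if ((nrow(v) > 0 && is.null(rownames(v))) ||
      (ncol(v) > 0 && is.null(colnames(v))))
    msgs <- c(msgs, "values must carry gene (row) and sample (column) names")
  if (anyDuplicated(rownames(v)))
    msgs <- c(msgs, "gene ids must be unique")
  if (length(object@scale) != 1L)
    msgs <- c(msgs, "scale must be a single string")
  else if (object@scale %in% c("counts", "FPKM", "TPM") &&
           any(v < 0, na.rm = TRUE))
    msgs <- c(msgs, sprintf("%s values must be non-negative", object@scale))
  if (ncol(info) > 0) {
    if (nrow(info) != nrow(v) ||
        (nrow(v) > 0 && !identical(rownames(info), rownames(v))))
      msgs <- c(msgs, "geneInfo rows must match value rows")
    need <- c("chrom", "start", "end", "strand", "tss")
    if (!all(need %in% colnames(info)))
      msgs <- c(msgs, "geneInfo needs chrom/start/end/strand/tss columns")
    else {
      plus <- info$strand == "+"
      bad <- (plus & info$tss != info$start) | (!plus & info$tss != info$end)
      if (any(bad, na.rm = TRUE))
        msgs <- c(msgs, "tss must equal start on '+' strand, end on '-' strand")
      if (any(info$start > info$end, na.rm = TRUE))
        msgs <- c(msgs, "gene start must be <= end")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' SampleCovariates: per-sample fixed effects and trait
#'
#' Sex and slaughter batch are categorical fixed effects, carcass weight a
#' continuous covariate; the trait column (intramuscular fat percentage in
#' the motivating design) is optional and `NA` when unmeasured.
#'
#' @slot sampleIds character vector of unique sample identifiers.
#' @slot sex factor, one level per sex.
#' @slot batch factor, one level per slaughter batch.
#' @slot weight numeric carcass weight (kg).
#' @slot trait numeric trait value, `NA` allowed.
#' @export
setClass("SampleCovariates",
         slots = c(sampleIds = "character", sex = "factor", batch = "factor",
                   weight = "numeric", trait = "numeric"))

setValidity("SampleCovariates", function(object) {
  n <- length(object@sampleIds)
  msgs <- character()
  if (anyDuplicated(object@sampleIds))
    msgs <- c(msgs, "sample ids must be unique")
  for (sl in c("sex", "batch", "weight", "trait"))
    if (length(slot(object, sl)) != n)
      msgs <- c(msgs, sprintf("'%s' must have one value per sample", sl))
  if (length(msgs)) msgs else TRUE
})

#' GwasSummary: per-SNP trait association p-values
#'
#' @slot table data.frame with columns `chrom`, `pos` (1-based bp) and `p`,
#'   sorted by (chrom, pos); p in (0, 1].
#' @export
setClass("GwasSummary", slots = c(table = "data.frame"))

setValidity("GwasSummary", function(object) {
  tab <- object@table
  msgs <- character()
  if (!all(c("chrom", "pos", "p") %in% colnames(tab)))
    msgs <- c(msgs, "table needs chrom/pos/p columns")
  else {
    if (any(tab$p <= 0 | tab$p > 1, na.rm = TRUE))
      msgs <- c(msgs, "p-values must lie in (0, 1]")
    o <- order(factor(tab$chrom, levels = unique(tab$chrom)), tab$pos)
    if (!identical(o, seq_len(nrow(tab))))
      msgs <- c(msgs, "rows must be sorted by (chrom, pos)")
  }
  if (length(msgs)) msgs else TRUE
})

#' ModuleAssignment: co-expression module labels and summary statistics
#'
#' @slot labels named character vector mapping gene id to module label; the
#'   reserved label `"unassigned"` marks genes outside any module.
#' @slot eigengenes numeric matrix, samples x modules (unit-norm columns).
#' @slot moduleTrait data.frame of per-module trait correlation (`module`,
#'   `r`, `p`, `n`); zero rows until computed.
#' @slot geneStats data.frame of per-gene statistics (`gene`, `module`,
#'   `gs_r`, `gs_p`, `mm_r`, `mm_p`, `critical`); zero rows until computed.
#' @export
setClass("ModuleAssignment",
         slots = c(labels = "character", eigengenes = "matrix",
                   moduleTrait = "data.frame", geneStats = "data.frame"))

setValidity("ModuleAssignment", function(object) {
  msgs <- character()
  if (is.null(names(object@labels)))
    msgs <- c(msgs, "labels must be named by gene id")
  mods <- setdiff(unique(object@labels), "unassigned")
  if (ncol(object@eigengenes) > 0 &&
      !all(sort(colnames(object@eigengenes)) == sort(mods)))
    msgs <- c(msgs, "eigengene columns must match module labels")
  if (length(msgs)) msgs else TRUE
})
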