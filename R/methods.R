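#' @include AllGenerics.R
NULL

# ---- constructors ----------------------------------------------------------

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix of alternative-allele counts (samples x SNPs),
#'   values in \{0, 1, 2, NA\}. Row/column names may be supplied here or via
#'   `sampleIds`/`snpIds`.
#' @param chrom,pos per-SNP chromosome label and 1-based position.
#' @param snpIds,sampleIds identifier vectors (default taken from dimnames).
#' @param sort reorder SNPs by (chrom, pos)? Default `TRUE`.
#' @return A [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(dosage, chrom, pos, snpIds = colnames(dosage),
                           sampleIds = rownames(dosage), sort = TRUE) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(ncol(dosage)))
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(nrow(dosage)))
  dimnames(dosage) <- list(sampleIds, snpIds)
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (sort) {
    o <- order(factor(chrom, levels = unique(chrom)), pos)
    dosage <- dosage[, o, drop = FALSE]
    chrom <- chrom[o]
    pos <- pos[o]
  }
  info <- DataFrame(chrom = chrom, pos = pos, row.names = colnames(dosage))
  new("GenotypeMatrix", dosage = dosage, snpInfo = info)
}

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes x samples.
#' @param geneInfo data.frame/DataFrame with per-gene `chrom`, `start`,
#'   `end`, `strand` (and optionally `tss`; derived strand-aware otherwise),
#'   or `NULL` for no annotation.
#' @param scale abundance scale tag: `"counts"`, `"FPKM"`, `"TPM"`,
#'   `"normalized"` or `"log2"`.
#' @param transform optional list describing the invertible map back to the
#'   latent linear scale (e.g. `list(name = "log2")`).
#' @return An [ExpressionMatrix-class].
#' @export
ExpressionMatrix <- function(values, geneInfo = NULL, scale = "FPKM",
                             transform = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("gene", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(geneInfo)) {
    info <- DataFrame(matrix(nrow = nrow(values), ncol = 0),
                      row.names = rownames(values))
  } else {
    info <- as(as.data.frame(geneInfo), "DataFrame")
    if (is.null(rownames(info)) || all(rownames(info) == seq_len(nrow(info))))
      rownames(info) <- rownames(values)
    if (!"tss" %in% colnames(info))
      info$tss <- ifelse(info$strand == "+", info$start, info$end)
    info <- info[rownames(values), , drop = FALSE]
  }
  new("ExpressionMatrix", values = values, geneInfo = info,
      scale = scale, transform = transform)
}

#' Construct SampleCovariates
#'
#' @param sampleIds sample identifiers.
#' @param sex,batch categorical covariates (coerced to factor).
#' @param weight continuous carcass weight (kg).
#' @param trait trait values (`NA` when unmeasured).
#' @return A [SampleCovariates-class].
#' @export
SampleCovariates <- function(sampleIds, sex, batch, weight,
                             trait = rep(NA_real_, length(sampleIds))) {
  new("SampleCovariates", sampleIds = as.character(sampleIds),
      sex = as.factor(sex), batch = as.factor(batch),
      weight = as.numeric(weight), trait = as.numeric(trait))
}

#' Construct a GwasSummary
#'
#' @param chrom,pos,p per-SNP chromosome, 1-based position and p-value.
#' @param snpId optional SNP identifiers.
#' @return A [GwasSummary-class], rows sorted by (chrom, pos).
#' @export
GwasSummary <- function(chrom, pos, p, snpId = NULL) {
  tab <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                    p = as.numeric(p), stringsAsFactors = FALSE)
  if (!is.null(snpId)) tab$snp_id <- as.character(snpId)
  o <- order(factor(tab$chrom, levels = unique(tab$chrom)), tab$pos)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  new("GwasSummary", table = tab)
}

# ---- accessors -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)
#' @rdname accessors
#' @export
setMethod("snpInfo", "GenotypeMatrix", function(x) x@snpInfo)
#' @rdname accessors
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x) colnames(x@dosage))
#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosage))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("geneInfo", "ExpressionMatrix", function(x) x@geneInfo)
#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("exprScale", "ExpressionMatrix", function(x) x@scale)

#' @rdname accessors
#' @export
setMethod("latentValues", "ExpressionMatrix", function(x) {
  tr <- x@transform
  if (!length(tr) || is.null(tr$name)) {
    if (identical(x@scale, "normalized") || identical(x@scale, "log2"))
      return(x@values)
    stop("no latent transform recorded for this ExpressionMatrix")
  }
  switch(tr$name,
         log2 = log2(x@values),
         identity = x@values,
         stop("unknown transform: ", tr$name))
})

#' @rdname accessors
#' @export
setMethod("sampleIds", "SampleCovariates", function(x) x@sampleIds)
#' @rdname accessors
#' @export
setMethod("covariateTable", "SampleCovariates", function(x)
  data.frame(sample_id = x@sampleIds, sex = x@sex, batch = x@batch,
             weight = x@weight, trait = x@trait, stringsAsFactors = FALSE))
#' @rdname accessors
#' @export
setMethod("traitValues", "SampleCovariates", function(x)
  stats::setNames(x@trait, x@sampleIds))
#' @rdname accessors
#' @export
setMethod("gwasTable", "GwasSummary", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModuleAssignment", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("eigengenes", "ModuleAssignment", function(x) x@eigengenes)
#' @rdname accessors
#' @export
setMethod("moduleTrait", "ModuleAssignment", function(x) x@moduleTrait)
#' @rdname accessors
#' @export
setMethod("geneStats", "ModuleAssignment", function(x) x@geneStats)

# ---- subsetting ------------------------------------------------------------

#' @describeIn GenotypeMatrix subset samples (i) and/or SNPs (j) by index or
#'   name; SNP order is preserved so position sorting is retained.
#' @param x,i,j,drop,... standard subsetting arguments (drop is ignored).
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  d <- x@dosage
  if (missing(i)) i <- seq_len(nrow(d))
  if (missing(j)) j <- seq_len(ncol(d))
  d <- d[i, j, drop = FALSE]
  info <- x@snpInfo[j, , drop = FALSE]
  new("GenotypeMatrix", dosage = d, snpInfo = info)
})

#' @describeIn ExpressionMatrix subset genes (i) and/or samples (j).
#' @param x,i,j,drop,... standard subsetting arguments (drop is ignored).
#' @export
setMethod("[", "ExpressionMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  new("ExpressionMatrix", values = v[i, j, drop = FALSE],
      geneInfo = x@geneInfo[i, , drop = FALSE],
      scale = x@scale, transform = x@transform)
})

#' @describeIn SampleCovariates subset samples by index or id.
#' @param x,i,j,drop,... standard subsetting arguments.
#' @export
setMethod("[", "SampleCovariates", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sampleIds)
  new("SampleCovariates", sampleIds = x@sampleIds[i], sex = droplevels(x@sex[i]),
      batch = droplevels(x@batch[i]), weight = x@weight[i], trait = x@trait[i])
})

# ---- show ------------------------------------------------------------------

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosage
  cat(sprintf("GenotypeMatrix: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(d), ncol(d), length(unique(object@snpInfo$chrom))))
  miss <- mean(is.na(d))
  cat(sprintf("  missing dosage rate: %.3f\n", miss))
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s scale]%s\n",
              nrow(object@values), ncol(object@values), object@scale,
              if (ncol(object@geneInfo)) " with annotation" else ""))
})

setMethod("show", "SampleCovariates", function(object) {
  cat(sprintf(
    "SampleCovariates: %d samples, %d sex level(s), %d batch(es), trait %s\n",
    length(object@sampleIds), nlevels(object@sex), nlevels(object@batch),
    if (all(is.na(object@trait))) "absent" else "present"))
})

setMethod("show", "GwasSummary", function(object) {
  cat(sprintf("GwasSummary: %d SNPs on %d chromosome(s), min p = %.3g\n",
              nrow(object@table), length(unique(object@table$chrom)),
              suppressWarnings(min(object@table$p))))
})

setMethod("show", "ModuleAssignment", function(object) {
  mods <- setdiff(unique(object@labels), "unassigned")
  cat(sprintf("ModuleAssignment: %d genes in %d module(s), %d unassigned\n",
              length(object@labels), length(mods),
              sum(object@labels == "unassigned")))
})
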