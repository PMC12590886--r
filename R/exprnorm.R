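#' @include methods.R
NULL

#' Filter to expressed genes (abundance > threshold in a strict majority)
#'
#' A gene is retained iff its abundance exceeds `minFpkm` in strictly more
#' than `minFraction` of the samples (both comparisons strict, so a gene at
#' exactly the threshold in every sample is dropped, and 40 of 80 samples is
#' not enough while 41 is).
#'
#' @param expr an [ExpressionMatrix-class] on a raw abundance scale
#'   (FPKM in the motivating design).
#' @param minFpkm abundance threshold (default 0.1).
#' @param minFraction sample-fraction threshold (default 0.5).
#' @return list with `expr` (filtered [ExpressionMatrix-class]) and
#'   `report` (n_genes_in, n_genes_retained, transform_name, retained flags).
#' @export
filterExpressed <- function(expr, minFpkm = 0.1, minFraction = 0.5) {
  v <- exprValues(expr)
  if (nrow(v) == 0 || ncol(v) == 0) stop("empty expression matrix")
  retained <- rowSums(v > minFpkm) > minFraction * ncol(v)
  list(expr = expr[which(retained), ],
       report = list(n_genes_in = nrow(v),
                     n_genes_retained = sum(retained),
                     transform_name = "expressed-filter",
                     retained = stats::setNames(retained, rownames(v))))
}

#' Rank-based inverse-normal transformation (per gene, across samples)
#'
#' Each gene's values are replaced by standard-normal quantiles of their
#' offset ranks: `qnorm((rank - c)/n)` with average ranks for ties. The
#' default offset `c = 0.5` makes the middle of three distinct values map to
#' exactly 0; the Blom variant `qnorm((rank - 3/8)/(n + 1/4))` is available.
#' The output is invariant to any strictly monotone per-gene transform of
#' the input.
#'
#' @param expr an [ExpressionMatrix-class] (any monotone abundance scale).
#' @param method `"offset"` (default) or `"blom"`.
#' @return An [ExpressionMatrix-class] on the `"normalized"` scale.
#' @export
rankInverseNormal <- function(expr, method = c("offset", "blom")) {
  method <- match.arg(method)
  v <- exprValues(expr)
  n <- ncol(v)
  if (n < 3) stop("need at least 3 samples to rank-normalize")
  z <- t(apply(v, 1, function(x) {
    r <- rank(x, ties.method = "average")
    if (method == "offset") stats::qnorm((r - 0.5) / n)
    else stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  }))
  dimnames(z) <- dimnames(v)
  ExpressionMatrix(z, geneInfo = if (ncol(geneInfo(expr)))
    as.data.frame(geneInfo(expr)) else NULL,
    scale = "normalized", transform = list(name = "identity"))
}

#' FPKM from raw counts
#'
#' FPKM = 1e9 * count / (geneLength * librarySize).
#'
#' @param counts counts matrix (genes x samples) or an
#'   [ExpressionMatrix-class] on the counts scale.
#' @param geneLengths per-gene length (bp), all > 0.
#' @param librarySizes per-sample library size; default `colSums(counts)`.
#' @return An [ExpressionMatrix-class] on the FPKM scale.
#' @export
computeFpkm <- function(counts, geneLengths, librarySizes = NULL) {
  em <- if (is(counts, "ExpressionMatrix")) counts else
    ExpressionMatrix(counts, scale = "counts")
  v <- exprValues(em)
  if (any(geneLengths <= 0)) stop("gene lengths must be > 0")
  librarySizes <- librarySizes %||% colSums(v)
  if (any(librarySizes <= 0)) stop("zero library size")
  fpkm <- 1e9 * sweep(v / geneLengths, 2, librarySizes, "/")
  ExpressionMatrix(fpkm, geneInfo = if (ncol(geneInfo(em)))
    as.data.frame(geneInfo(em)) else NULL, scale = "FPKM")
}

#' TPM from raw counts
#'
#' Length-normalized rates rescaled so each sample sums to 1e6.
#'
#' @inheritParams computeFpkm
#' @return An [ExpressionMatrix-class] on the TPM scale.
#' @export
computeTpm <- function(counts, geneLengths) {
  em <- if (is(counts, "ExpressionMatrix")) counts else
    ExpressionMatrix(counts, scale = "counts")
  v <- exprValues(em)
  if (any(geneLengths <= 0)) stop("gene lengths must be > 0")
  rate <- v / geneLengths
  tot <- colSums(rate)
  if (any(tot <= 0)) stop("zero library size")
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  ExpressionMatrix(tpm, geneInfo = if (ncol(geneInfo(em)))
    as.data.frame(geneInfo(em)) else NULL, scale = "TPM")
}
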