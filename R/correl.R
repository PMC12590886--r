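#' @include methods.R
NULL

#' Adjust a per-sample vector for fixed effects
#'
#' OLS of the values on intercept + sex and batch dummies + carcass weight;
#' returns the (mean-zero) residuals. Collinear dummies are dropped with a
#' warning.
#'
#' @param values per-sample numeric vector (named by sample id or aligned
#'   with `cov`).
#' @param cov a [SampleCovariates-class].
#' @return residual vector (named by sample id).
#' @export
adjustCovariates <- function(values, cov) {
  ids <- sampleIds(cov)
  if (!is.null(names(values))) values <- values[ids]
  stopifnot(length(values) == length(ids), !anyNA(values))
  X <- .covariateDesign(cov)
  fit <- .olsFit(X, values)
  if (fit$rank < ncol(X))
    warning("rank-deficient covariate design; dropped: ",
            paste(colnames(X)[is.na(fit$coef)], collapse = ", "))
  stats::setNames(fit$residuals, ids)
}

#' Covariate-adjusted expression-trait correlation screen
#'
#' The trait is adjusted once for sex, batch and carcass weight; each gene's
#' log2 expression is adjusted the same way; Pearson correlation is computed
#' between the two residual vectors with the plain n - 2 degrees-of-freedom
#' t-test, and Benjamini-Hochberg q-values are taken across all genes.
#'
#' @param expr an [ExpressionMatrix-class]. Raw abundances (counts/FPKM/TPM)
#'   are transformed as `log2(x + pseudocount)`; `"log2"` or `"normalized"`
#'   scales are used as-is.
#' @param cov a [SampleCovariates-class] with the trait filled.
#' @param pseudocount added before the log2 transform (default 1).
#' @param qThreshold significance threshold on q (default 0.05, inclusive).
#' @return data.frame sorted by q then p: gene_id, r, p, q, significant.
#' @export
traitCorrelation <- function(expr, cov, pseudocount = 1, qThreshold = 0.05) {
  samples <- .alignSamples(sampleIds(expr), sampleIds(cov))
  if (length(samples) < 4) stop("need at least 4 samples")
  covA <- cov[samples]
  y <- traitValues(covA)
  if (anyNA(y)) stop("trait missing for some samples")
  v <- exprValues(expr)[, samples, drop = FALSE]
  if (exprScale(expr) %in% c("counts", "FPKM", "TPM"))
    v <- log2(v + pseudocount)
  yr <- adjustCovariates(y, covA)
  X <- .covariateDesign(covA)
  qrX <- qr(X)
  res <- t(apply(v, 1, function(g) {
    gr <- qr.resid(qrX, g)
    ct <- stats::cor.test(gr, yr, method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  }))
  out <- data.frame(gene_id = rownames(v), r = res[, "r"], p = res[, "p"],
                    stringsAsFactors = FALSE)
  out$q <- bhFdr(out$p)
  out$significant <- out$q <= qThreshold
  out <- out[order(out$q, out$p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
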