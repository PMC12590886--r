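#' @importFrom stats lm.fit model.matrix reformulate qnorm pnorm pt rnorm
#'   rbinom runif sd cor cor.test p.adjust setNames quantile IQR hclust
#'   cutree dist as.dist t.test complete.cases var
#' @importFrom utils read.delim write.table packageVersion
NULL

# OLS with pivot-aware standard errors; aliased columns get NA coefficients.
.olsFit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  r <- fit$rank
  df <- n - r
  rss <- sum(fit$residuals^2)
  sigma2 <- if (df > 0) rss / df else NA_real_
  se <- rep(NA_real_, ncol(X))
  if (r > 0) {
    piv <- fit$qr$pivot[seq_len(r)]
    R <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
    xtxinv <- chol2inv(R)
    se[piv] <- sqrt(pmax(diag(xtxinv), 0) * sigma2)
  }
  names(se) <- colnames(X)
  list(coef = fit$coefficients, se = se, df = df, sigma2 = sigma2,
       residuals = fit$residuals, fitted = y - fit$residuals, rank = r)
}

# Fixed-effect design: intercept + sex and batch dummies + carcass weight.
# Single-level factors contribute nothing beyond the intercept and are
# silently absorbed.
.covariateDesign <- function(cov, samples = NULL) {
  tab <- data.frame(sex = droplevels(cov@sex), batch = droplevels(cov@batch),
                    weight = cov@weight, row.names = cov@sampleIds)
  if (!is.null(samples)) tab <- tab[samples, , drop = FALSE]
  terms <- c(if (nlevels(tab$sex) >= 2) "sex",
             if (nlevels(tab$batch) >= 2) "batch",
             "weight")
  X <- stats::model.matrix(stats::reformulate(terms), tab)
  rownames(X) <- rownames(tab)
  X
}

# Deterministic sample alignment: sorted intersection of ids.
.alignSamples <- function(...) {
  ids <- list(...)
  out <- Reduce(intersect, ids)
  if (!length(out)) stop("no samples shared across inputs")
  sort(out)
}

.meanImpute <- function(x) {
  miss <- is.na(x)
  if (any(miss)) x[miss] <- mean(x[!miss])
  x
}

# Two-sided p-value for a Pearson correlation on n observations (df = n - 2).
.corPvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
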