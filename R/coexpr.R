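#' @include methods.R
NULL

# Expression matrix (genes x samples) on a clustering-friendly scale:
# log2(x + 1) for raw abundances, values as-is otherwise.
.coexprMatrix <- function(expr, pseudocount = 1) {
  v <- exprValues(expr)
  if (exprScale(expr) %in% c("counts", "FPKM", "TPM"))
    log2(v + pseudocount)
  else v
}

#' Detect outlier samples by hierarchical clustering
#'
#' Samples are clustered by average-linkage on the Euclidean distance of
#' their expression profiles and the tree is cut at `cutHeight`; the largest
#' resulting cluster is retained, everything else is flagged as outliers.
#' The default height is `median(h) + 6 * IQR(h)` over the merge heights:
#' wide enough that the top merges of a homogeneous cohort stay below it,
#' while samples with a global expression artifact join far above.
#'
#' @param expr an [ExpressionMatrix-class] (raw scales are log2(x+1)
#'   transformed for clustering).
#' @param cutHeight tree cut height; `NULL` for the default rule.
#' @return list: `retained` and `removed` sample ids, `cutHeight`, `tree`.
#' @export
detectOutlierSamples <- function(expr, cutHeight = NULL) {
  m <- .coexprMatrix(expr)
  if (ncol(m) < 10) stop("need at least 10 samples")
  tree <- stats::hclust(stats::dist(t(m)), method = "average")
  cutHeight <- cutHeight %||%
    (stats::median(tree$height) + 6 * stats::IQR(tree$height))
  cl <- stats::cutree(tree, h = cutHeight)
  sizes <- table(cl)
  if (max(sizes) == 1)
    stop("all samples are singletons at this height; increase cutHeight")
  main <- as.integer(names(sizes)[which.max(sizes)])
  list(retained = colnames(m)[cl == main],
       removed = colnames(m)[cl != main],
       cutHeight = cutHeight, tree = tree)
}

#' Unsigned co-expression adjacency
#'
#' `a_ij = |cor(g_i, g_j)|^power` with zero diagonal.
#'
#' @param expr [ExpressionMatrix-class] or genes x samples matrix.
#' @param power soft-thresholding power.
#' @return genes x genes adjacency matrix.
#' @export
adjacencyMatrix <- function(expr, power = 6) {
  m <- if (is(expr, "ExpressionMatrix")) .coexprMatrix(expr) else
    as.matrix(expr)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene(s) present; filter before building the network")
  a <- abs(stats::cor(t(m)))^power
  diag(a) <- 0
  a
}

#' Pick the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the connectivity distribution is binned
#' (equal-width bins of k) and the fit R^2 of log10(frequency) on
#' log10(mean k) is computed; the fit counts only when the slope is
#' negative. The chosen power is the smallest with R^2 >= `r2Target`, else
#' the argmax of R^2.
#'
#' @param expr [ExpressionMatrix-class] or genes x samples matrix (constant
#'   genes are excluded first).
#' @param powers candidate powers (default 1:20).
#' @param r2Target target fit (default 0.8).
#' @param nBins connectivity histogram bins (default 10).
#' @return list: `power`, and `table` of per-power R^2 and mean k.
#' @export
pickSoftPower <- function(expr, powers = 1:20, r2Target = 0.8, nBins = 10) {
  m <- if (is(expr, "ExpressionMatrix")) .coexprMatrix(expr) else
    as.matrix(expr)
  m <- m[apply(m, 1, stats::sd) > 0, , drop = FALSE]
  if (nrow(m) < 50) stop("need at least 50 non-constant genes")
  absCor <- abs(stats::cor(t(m)))
  diag(absCor) <- 0
  fits <- lapply(powers, function(p) {
    k <- colSums(absCor^p)
    if (stats::var(k) == 0)
      return(data.frame(power = p, r2 = 0, slope = NA_real_,
                        mean_k = mean(k)))
    br <- seq(min(k), max(k), length.out = nBins + 1)
    bin <- cut(k, breaks = br, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    mk <- tapply(k, bin, mean)
    keep <- !is.na(freq) & freq > 0 & mk > 0
    if (sum(keep) < 3)
      return(data.frame(power = p, r2 = 0, slope = NA_real_,
                        mean_k = mean(k)))
    fit <- stats::lm(log10(freq[keep] / length(k)) ~ log10(mk[keep]))
    slope <- stats::coef(fit)[2]
    r2 <- summary(fit)$r.squared * (slope < 0)
    data.frame(power = p, r2 = r2, slope = slope, mean_k = mean(k))
  })
  tab <- do.call(rbind, fits)
  rownames(tab) <- NULL
  hit <- which(tab$r2 >= r2Target)
  power <- if (length(hit)) tab$power[hit[1]] else
    tab$power[which.max(tab$r2)]
  list(power = power, table = tab)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with a
#' unit diagonal, where `k_i = sum_u a_iu`.
#'
#' @param adjacency symmetric adjacency with zero diagonal, entries in
#'   `[0, 1]`.
#' @return symmetric TOM with entries in `[0, 1]` and unit diagonal.
#' @export
tomSimilarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-12)) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- colSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Module eigengene (first principal component of standardized expression)
#'
#' The per-sample eigengene is the first right singular vector of the
#' gene-standardized module matrix, unit norm, with its sign fixed so the
#' mean correlation with member genes is positive.
#'
#' @param exprSubset genes x samples matrix (module members) or an
#'   [ExpressionMatrix-class].
#' @return named per-sample numeric vector.
#' @export
moduleEigengene <- function(exprSubset) {
  m <- if (is(exprSubset, "ExpressionMatrix")) .coexprMatrix(exprSubset)
  else as.matrix(exprSubset)
  if (nrow(m) < 2) stop("module needs at least 2 genes")
  sds <- apply(m, 1, stats::sd)
  if (all(sds == 0)) stop("rank-0 module (all genes constant)")
  ms <- (m[sds > 0, , drop = FALSE] - rowMeans(m[sds > 0, , drop = FALSE])) /
    sds[sds > 0]
  sv <- svd(ms, nu = 0, nv = 1)
  e <- drop(sv$v)
  s <- mean(ms %*% e)
  if (s < 0) e <- -e
  stats::setNames(e, colnames(m))
}

#' Cut the TOM dendrogram into modules and merge similar ones
#'
#' Average-linkage clustering on dissimilarity `1 - TOM`, cut at a static
#' height. Because soft thresholding compresses TOM values, the default
#' height is tree-relative — the 0.99 quantile of the merge heights — which
#' yields many small pure clusters; clusters (of at least 2 genes) whose
#' eigengenes correlate above `1 - mergeHeight` are then merged iteratively
#' (most-correlated pair first), reassembling each module from its
#' fragments. Only after merging are clusters below `minModuleSize` set to
#' `"unassigned"`. Modules are labelled M1, M2, ... by decreasing size.
#'
#' @param tom TOM from [tomSimilarity()] (gene names as dimnames).
#' @param expr [ExpressionMatrix-class] or genes x samples matrix covering
#'   the TOM's genes (used for eigengene merging and output eigengenes).
#' @param minModuleSize smallest reportable module (default 30).
#' @param cutHeight static cut height on 1 - TOM; `NULL` (default) uses the
#'   0.99 quantile of the dendrogram merge heights.
#' @param mergeHeight eigengene-dissimilarity merge threshold (default
#'   0.25, i.e. merge while any pair of cluster eigengenes has cor > 0.75).
#' @return A [ModuleAssignment-class] (labels and eigengenes; trait
#'   statistics are added by [analyzeModules()]).
#' @export
cutModules <- function(tom, expr, minModuleSize = 30, cutHeight = NULL,
                       mergeHeight = 0.25) {
  m <- if (is(expr, "ExpressionMatrix")) .coexprMatrix(expr) else
    as.matrix(expr)
  genes <- rownames(tom)
  stopifnot(!is.null(genes), all(genes %in% rownames(m)))
  m <- m[genes, , drop = FALSE]
  emptyE <- matrix(numeric(), ncol(m), 0,
                   dimnames = list(colnames(m), NULL))
  if (length(genes) < minModuleSize) {
    warning("fewer genes than minModuleSize; all unassigned")
    return(new("ModuleAssignment",
               labels = stats::setNames(rep("unassigned", length(genes)),
                                        genes),
               eigengenes = emptyE,
               moduleTrait = data.frame(), geneStats = data.frame()))
  }
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cutHeight <- cutHeight %||% unname(stats::quantile(tree$height, 0.99))
  lab <- stats::setNames(as.character(stats::cutree(tree, h = cutHeight)),
                         genes)

  # iteratively merge the most-correlated cluster eigengenes
  eigenOf <- function(mod) moduleEigengene(m[names(lab)[lab == mod], ,
                                             drop = FALSE])
  repeat {
    mods <- names(which(table(lab) >= 2))
    if (length(mods) < 2) break
    E <- vapply(mods, eigenOf, numeric(ncol(m)))
    cc <- stats::cor(E)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[top[1], top[2]] <= 1 - mergeHeight) break
    a <- mods[top[1]]
    b <- mods[top[2]]
    into <- if (sum(lab == a) >= sum(lab == b)) a else b
    lab[lab %in% c(a, b)] <- into
  }
  sizes <- table(lab)
  lab[lab %in% names(sizes)[sizes < minModuleSize]] <- "unassigned"

  # canonical labels: M1, M2, ... by decreasing size, gene order tie-break
  mods <- setdiff(unique(lab), "unassigned")
  if (length(mods)) {
    sz <- vapply(mods, function(x) sum(lab == x), numeric(1))
    first <- vapply(mods, function(x) which(lab == x)[1], numeric(1))
    mods <- mods[order(-sz, first)]
    newNames <- stats::setNames(paste0("M", seq_along(mods)), mods)
    lab[lab != "unassigned"] <- newNames[lab[lab != "unassigned"]]
  }
  mods <- setdiff(unique(lab), "unassigned")
  E <- if (length(mods))
    vapply(sort(mods), eigenOf, numeric(ncol(m))) else emptyE
  if (length(mods)) rownames(E) <- colnames(m)
  new("ModuleAssignment", labels = lab, eigengenes = as.matrix(E),
      moduleTrait = data.frame(), geneStats = data.frame())
}

#' Module-trait relationships
#'
#' Pearson correlation of each module eigengene with the trait, with the
#' usual t-distribution p-value on n - 2 degrees of freedom.
#'
#' @param assignment a [ModuleAssignment-class].
#' @param trait trait vector named by (or aligned with) the eigengene
#'   samples.
#' @return data.frame: module, r, p, n.
#' @export
moduleTraitRelationships <- function(assignment, trait) {
  E <- eigengenes(assignment)
  if (!ncol(E)) return(data.frame(module = character(), r = numeric(),
                                  p = numeric(), n = integer()))
  if (!is.null(names(trait))) trait <- trait[rownames(E)]
  if (stats::var(trait) == 0) stop("constant trait")
  n <- nrow(E)
  r <- drop(stats::cor(E, trait))
  data.frame(module = colnames(E), r = r, p = .corPvalue(r, n), n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene module statistics: gene significance and module membership
#'
#' GS is the Pearson correlation of each gene with the trait; MM the
#' correlation with the gene's own module eigengene (NA for unassigned
#' genes). Both come with t-distribution p-values.
#'
#' @param expr [ExpressionMatrix-class] or genes x samples matrix.
#' @param assignment a [ModuleAssignment-class].
#' @param trait trait vector aligned with the samples.
#' @return data.frame: gene, module, gs_r, gs_p, mm_r, mm_p.
#' @export
moduleGeneStatistics <- function(expr, assignment, trait) {
  m <- if (is(expr, "ExpressionMatrix")) .coexprMatrix(expr) else
    as.matrix(expr)
  lab <- moduleLabels(assignment)
  E <- eigengenes(assignment)
  m <- m[names(lab), rownames(E), drop = FALSE]
  if (!is.null(names(trait))) trait <- trait[rownames(E)]
  n <- ncol(m)
  gs <- drop(stats::cor(t(m), trait))
  mm <- rep(NA_real_, length(lab))
  for (mod in colnames(E)) {
    ix <- which(lab == mod)
    mm[ix] <- drop(stats::cor(t(m[ix, , drop = FALSE]), E[, mod]))
  }
  data.frame(gene = names(lab), module = unname(lab), gs_r = unname(gs),
             gs_p = .corPvalue(unname(gs), n), mm_r = mm,
             mm_p = ifelse(is.na(mm), NA_real_, .corPvalue(mm, n)),
             stringsAsFactors = FALSE)
}

#' Full module-trait analysis: MTR, GS/MM and critical genes
#'
#' Fills a [ModuleAssignment-class] with module-trait relationships and
#' per-gene statistics, flagging critical genes: GS p and MM p both below
#' `alpha` inside modules whose MTR p is below `mtrAlpha` (or inside an
#' explicit `criticalModules` set).
#'
#' @param expr [ExpressionMatrix-class] or matrix used for the network.
#' @param assignment a [ModuleAssignment-class] from [cutModules()].
#' @param trait trait vector aligned with the retained samples.
#' @param mtrAlpha module-trait significance level (default 0.01).
#' @param alpha GS/MM significance level (default 0.01).
#' @param criticalModules explicit module set; default all MTR-significant
#'   modules.
#' @return the updated [ModuleAssignment-class].
#' @export
analyzeModules <- function(expr, assignment, trait, mtrAlpha = 0.01,
                           alpha = 0.01, criticalModules = NULL) {
  mtr <- moduleTraitRelationships(assignment, trait)
  gs <- moduleGeneStatistics(expr, assignment, trait)
  criticalModules <- criticalModules %||% mtr$module[mtr$p < mtrAlpha]
  gs$critical <- gs$module %in% criticalModules &
    !is.na(gs$mm_p) & gs$gs_p < alpha & gs$mm_p < alpha
  assignment@moduleTrait <- mtr
  assignment@geneStats <- gs
  assignment
}
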