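#' @include correl.R coexpr.R pqtl.R exprnorm.R synthio.R
NULL

#' Intersect the four evidence streams into a candidate report
#'
#' Genes are flagged by membership in the cis-eQTL, pQTL-colocalization,
#' critical-module and correlation-significant sets; the tier is the number
#' of flags set (4-way candidates carry all four). Candidates are sorted by
#' tier, then correlation q (when a correlation table is supplied), then
#' gene id.
#'
#' @param eqtlGenes genes with a significant cis-eQTL.
#' @param colocGenes genes whose significant cis-eQTLs overlap the pQTL
#'   interval.
#' @param criticalGenes critical genes from the co-expression analysis.
#' @param corrGenes correlation-significant genes.
#' @param corrTable optional data.frame from [traitCorrelation()] used for
#'   within-tier ordering and reporting r/q.
#' @return list with `candidates` (per-gene flags and tier) and `venn`
#'   (counts per flag combination, keys like `"eqtl+coloc"`).
#' @export
intersectEvidence <- function(eqtlGenes, colocGenes, criticalGenes,
                              corrGenes, corrTable = NULL) {
  sets <- list(eqtl = unique(eqtlGenes), coloc = unique(colocGenes),
               module = unique(criticalGenes), corr = unique(corrGenes))
  genes <- sort(Reduce(union, sets))
  if (!length(genes)) {
    warning("no genes in any evidence stream")
    return(list(candidates = data.frame(
      gene_id = character(), eqtl = logical(), coloc = logical(),
      module = logical(), corr = logical(), tier = integer()),
      venn = integer()))
  }
  flags <- sapply(sets, function(s) genes %in% s)
  flags <- matrix(flags, nrow = length(genes),
                  dimnames = list(genes, names(sets)))
  tier <- rowSums(flags)
  out <- data.frame(gene_id = genes, flags, tier = tier,
                    stringsAsFactors = FALSE)
  if (!is.null(corrTable)) {
    ix <- match(out$gene_id, corrTable$gene_id)
    out$r <- corrTable$r[ix]
    out$q <- corrTable$q[ix]
    out <- out[order(-out$tier, out$q, out$gene_id), , drop = FALSE]
  } else {
    out <- out[order(-out$tier, out$gene_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  combo <- apply(flags, 1, function(f)
    paste(names(sets)[f], collapse = "+"))
  venn <- table(combo)
  list(candidates = out, venn = stats::setNames(as.integer(venn),
                                                names(venn)))
}

#' Run the full integrative pipeline on a synthetic cohort
#'
#' Simulates the cohort, then executes every stage in order: genotype QC;
#' expressed-gene filtering and rank-based inverse-normal normalization;
#' cis-eQTL scan; single-SNP trait GWAS and 2-LOD pQTL interval;
#' pQTL/cis-eQTL colocalization; outlier-sample removal and the weighted
#' co-expression network (soft power, TOM, modules, eigengenes, MTR, GS/MM);
#' covariate-adjusted trait correlation; permutation association and a
#' genotype-stratified trait summary for the top colocalized gene; and the
#' four-way evidence intersection.
#'
#' @param config a [simulationConfig()].
#' @param outdir optional directory for per-stage TSV/BED/JSON outputs.
#' @param cisWindow cis window (bp).
#' @param pGenomewide,pSuggestive eQTL significance thresholds.
#' @param mtrAlpha,gsAlpha module-trait and GS/MM significance levels.
#' @param corrQ correlation q threshold.
#' @param nPerm permutations for the top-gene association test.
#' @param softPowers candidate soft-thresholding powers.
#' @param verbose log stage progress via `message()`?
#' @return list with every stage's output (`data`, `qc`, `scan`, `gwas`,
#'   `pqtl`, `coloc`, `modules`, `correlation`, `permutation`, `stratified`,
#'   `evidence`, `manifest`).
#' @export
runPipeline <- function(config = simulationConfig(), outdir = NULL,
                        cisWindow = 1e6, pGenomewide = 5e-8,
                        pSuggestive = 5e-6, mtrAlpha = 0.01, gsAlpha = 0.01,
                        corrQ = 0.05, nPerm = 1e4, softPowers = 1:20,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message("[imfscan] ", ...)
  stage <- function(name, fn) {
    say(name)
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  data <- stage("simulate", function() {
    geno <- simulateGenotypes(config)
    cov <- simulateCovariates(config)
    expr <- simulateExpression(geno, cov, config)
    cov <- simulateTrait(expr, cov, config)
    list(geno = geno, cov = cov, expr = expr,
         layout = simulationLayout(config))
  })
  qc <- stage("genotype QC", function() qcGenotypes(data$geno))
  norm <- stage("normalize", function() {
    filt <- filterExpressed(data$expr)
    list(filtered = filt$expr, report = filt$report,
         normalized = rankInverseNormal(filt$expr))
  })
  scan <- stage("cis-eQTL scan", function()
    eqtlScan(norm$normalized, qc$genotypes, data$cov, window = cisWindow,
             pGenomewide = pGenomewide, pSuggestive = pSuggestive))
  gwas <- stage("trait GWAS", function() gwasScan(qc$genotypes, data$cov))
  pqtl <- stage("2-LOD pQTL interval", function() lodDropInterval(gwas))
  coloc <- stage("colocalization", function() colocalize(pqtl, scan))

  modules <- stage("co-expression network", function() {
    out <- detectOutlierSamples(norm$filtered)
    exprR <- norm$filtered[, out$retained]
    power <- pickSoftPower(exprR, powers = softPowers)
    tom <- tomSimilarity(adjacencyMatrix(exprR, power$power))
    ma <- cutModules(tom, exprR)
    trait <- traitValues(data$cov)[out$retained]
    ma <- analyzeModules(exprR, ma, trait, mtrAlpha = mtrAlpha,
                         alpha = gsAlpha)
    list(assignment = ma, outliers = out, power = power)
  })
  correlation <- stage("trait correlation", function()
    traitCorrelation(norm$filtered, data$cov, qThreshold = corrQ))

  permutation <- NULL
  stratified <- NULL
  if (nrow(coloc) > 0) {
    topGene <- coloc$gene_id[1]
    topSnps <- coloc$snps[[1]]
    permutation <- stage("permutation association", function()
      permutationAssoc(data$geno[, topSnps], data$cov, nPerm = nPerm,
                       seed = config$seed))
    stratified <- stage("genotype-stratified trait", function() {
      peak <- scan[scan$gene_id == topGene & scan$snp_id %in% topSnps, ]
      peakSnp <- peak$snp_id[which.min(peak$p)]
      genotypeStratifiedTest(dosage(data$geno)[, peakSnp],
                             traitValues(data$cov))
    })
  }

  evidence <- stage("evidence intersection", function() {
    gsTab <- geneStats(modules$assignment)
    intersectEvidence(
      eqtlGenes = unique(scan$gene_id[scan$significant_sugg &
                                        scan$relation == "cis"]),
      colocGenes = coloc$gene_id,
      criticalGenes = gsTab$gene[gsTab$critical],
      corrGenes = correlation$gene_id[correlation$significant],
      corrTable = correlation)
  })

  manifest <- list(
    package = "imfscan",
    version = as.character(utils::packageVersion("imfscan")),
    seed = config$seed,
    thresholds = list(cis_window = cisWindow, p_genomewide = pGenomewide,
                      p_suggestive = pSuggestive, mtr_alpha = mtrAlpha,
                      gs_mm_alpha = gsAlpha, correlation_q = corrQ,
                      lod_drop = 2, n_perm = nPerm),
    cohort = list(n_samples = config$nSamples, n_snps = config$nSnps,
                  n_genes = config$nGenes))

  result <- list(data = data, qc = qc, norm = norm, scan = scan,
                 gwas = gwas, pqtl = pqtl, coloc = coloc, modules = modules,
                 correlation = correlation, permutation = permutation,
                 stratified = stratified, evidence = evidence,
                 manifest = manifest)
  if (!is.null(outdir)) .writePipelineOutputs(result, outdir)
  result
}

.writePipelineOutputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tab, name) {
    tab <- as.data.frame(tab)
    listCols <- vapply(tab, is.list, logical(1))
    for (cn in names(tab)[listCols])
      tab[[cn]] <- vapply(tab[[cn]], paste, character(1), collapse = ",")
    utils::write.table(tab, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(result$scan, "eqtl.tsv")
  writeGwas(result$gwas, file.path(outdir, "gwas.tsv"))
  writeIntervals(result$pqtl, file.path(outdir, "pqtl_interval.bed"))
  w(result$coloc, "colocalization.tsv")
  ma <- result$modules$assignment
  w(data.frame(gene = names(moduleLabels(ma)),
               module = unname(moduleLabels(ma))), "modules.tsv")
  w(moduleTrait(ma), "module_trait.tsv")
  w(geneStats(ma), "gene_statistics.tsv")
  w(result$correlation, "correlation.tsv")
  w(result$evidence$candidates, "candidates.tsv")
  jsonlite::write_json(as.list(result$evidence$venn),
                       file.path(outdir, "venn.json"), auto_unbox = TRUE)
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
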