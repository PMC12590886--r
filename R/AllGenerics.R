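#' @include AllClasses.R
NULL

#' Accessors for the imfscan data classes
#'
#' `dosage()` returns the samples x SNPs dosage matrix; `snpInfo()` the
#' per-SNP metadata; `exprValues()` the genes x samples abundance matrix;
#' `geneInfo()` the per-gene annotation; `exprScale()` the declared abundance
#' scale; `latentValues()` the expression mapped back to its latent linear
#' scale through the recorded transform; `sampleIds()`, `snpIds()` and
#' `geneIds()` the identifier vectors; `covariateTable()` the per-sample
#' covariates as a data.frame; `traitValues()` the trait vector;
#' `gwasTable()` the per-SNP summary table; `moduleLabels()`,
#' `eigengenes()`, `moduleTrait()` and `geneStats()` the components of a
#' [ModuleAssignment-class].
#'
#' @param x an imfscan object.
#' @return The component named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))
#' @rdname accessors
#' @export
setGeneric("latentValues", function(x) standardGeneric("latentValues"))
#' @rdname accessors
#' @export
setGeneric("covariateTable", function(x) standardGeneric("covariateTable"))
#' @rdname accessors
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))
#' @rdname accessors
#' @export
setGeneric("gwasTable", function(x) standardGeneric("gwasTable"))
#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))
#' @rdname accessors
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))
#' @rdname accessors
#' @export
setGeneric("moduleTrait", function(x) standardGeneric("moduleTrait"))
#' @rdname accessors
#' @export
setGeneric("geneStats", function(x) standardGeneric("geneStats"))
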