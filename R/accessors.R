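#' Accessors for awmnet containers
#'
#' Small accessor generics so user code never reaches into slots:
#' `dosages()` and `snpInfo()` for [GenotypePanel-class],
#' `traitValues()`, `covariates()` and `traitSpec()` for [TraitTable-class],
#' `grmMatrix()` and `nSnpsUsed()` for [GRM-class],
#' `assocBeta()`, `assocSE()`, `assocP()` for [AssocResults-class],
#' `awmValues()`, `geneToSnp()` and `keyTrait()` for [AWMatrix-class],
#' `networkNodes()` and `networkEdges()` for [CoAssocNetwork-class].
#'
#' @param x an awmnet object.
#' @return The slot contents (matrix or data.frame as documented on the
#'   class pages); `sampleIds()` returns a character vector.
#' @name accessors
#' @aliases dosages snpInfo sampleIds traitValues covariates traitSpec
#'   grmMatrix nSnpsUsed assocBeta assocSE assocP awmValues geneToSnp
#'   keyTrait networkNodes networkEdges
#' @examples
#' cfg <- simConfig(nIndividuals = 20, nSnps = 50, nChromosomes = 2,
#'                  nTraits = 4, nModules = 2, genesPerModule = 3,
#'                  seed = 1)
#' sim <- simulateGenotypes(cfg)
#' dim(dosages(sim$geno))
#' head(snpInfo(sim$geno))
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))
#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))
#' @rdname accessors
#' @export
setGeneric("traitSpec", function(x) standardGeneric("traitSpec"))
#' @rdname accessors
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))
#' @rdname accessors
#' @export
setGeneric("nSnpsUsed", function(x) standardGeneric("nSnpsUsed"))
#' @rdname accessors
#' @export
setGeneric("assocBeta", function(x) standardGeneric("assocBeta"))
#' @rdname accessors
#' @export
setGeneric("assocSE", function(x) standardGeneric("assocSE"))
#' @rdname accessors
#' @export
setGeneric("assocP", function(x) standardGeneric("assocP"))
#' @rdname accessors
#' @export
setGeneric("awmValues", function(x) standardGeneric("awmValues"))
#' @rdname accessors
#' @export
setGeneric("geneToSnp", function(x) standardGeneric("geneToSnp"))
#' @rdname accessors
#' @export
setGeneric("keyTrait", function(x) standardGeneric("keyTrait"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypePanel", function(x) x@dosage)
#' @rdname accessors
#' @export
setMethod("snpInfo", "GenotypePanel", function(x) x@snpInfo)
#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypePanel", function(x) rownames(x@dosage))
#' @rdname accessors
#' @export
setMethod("sampleIds", "TraitTable", function(x) rownames(x@traits))
#' @rdname accessors
#' @export
setMethod("traitValues", "TraitTable", function(x) x@traits)
#' @rdname accessors
#' @export
setMethod("covariates", "TraitTable", function(x) x@covariates)
#' @rdname accessors
#' @export
setMethod("traitSpec", "TraitTable", function(x) x@spec)
#' @rdname accessors
#' @export
setMethod("grmMatrix", "GRM", function(x) x@matrix)
#' @rdname accessors
#' @export
setMethod("nSnpsUsed", "GRM", function(x) x@nSnpsUsed)
#' @rdname accessors
#' @export
setMethod("assocBeta", "AssocResults", function(x) x@beta)
#' @rdname accessors
#' @export
setMethod("assocSE", "AssocResults", function(x) x@se)
#' @rdname accessors
#' @export
setMethod("assocP", "AssocResults", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("snpInfo", "AssocResults", function(x) x@snpInfo)
#' @rdname accessors
#' @export
setMethod("awmValues", "AWMatrix", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("geneToSnp", "AWMatrix", function(x) x@geneToSnp)
#' @rdname accessors
#' @export
setMethod("keyTrait", "AWMatrix", function(x) x@keyTrait)
#' @rdname accessors
#' @export
setMethod("networkNodes", "CoAssocNetwork", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("networkEdges", "CoAssocNetwork", function(x) x@edges)

#' @rdname GenotypePanel-class
#' @export
setMethod("show", "GenotypePanel", function(object) {
  d <- object@dosage
  cat(sprintf("GenotypePanel: %d individuals x %d SNPs\n", nrow(d), ncol(d)))
  si <- object@snpInfo
  mapped <- sum(si$chrom != "0" & si$pos > 0)
  cat(sprintf("  mapped SNPs: %d | chromosomes: %d | mean MAF: %.3f | missing: %.2f%%\n",
              mapped, length(unique(si$chrom[si$chrom != "0"])),
              mean(si$maf, na.rm = TRUE), 100 * mean(is.na(d))))
})

#' @rdname TraitTable-class
#' @export
setMethod("show", "TraitTable", function(object) {
  cat(sprintf("TraitTable: %d individuals x %d traits\n",
              nrow(object@traits), ncol(object@traits)))
  lab <- sum(object@spec$batchFactor == "labBatch")
  cat(sprintf("  covariates: sex (%d levels), batch (%d), labBatch (%d); %d lab-batch traits\n",
              nlevels(object@covariates$sex), nlevels(object@covariates$batch),
              nlevels(object@covariates$labBatch), lab))
})

#' @rdname GRM-class
#' @export
setMethod("show", "GRM", function(object) {
  cat(sprintf("GRM: %d x %d from %d SNPs | mean diagonal %.4f\n",
              nrow(object@matrix), ncol(object@matrix), object@nSnpsUsed,
              mean(diag(object@matrix))))
})

#' @rdname AssocResults-class
#' @export
setMethod("show", "AssocResults", function(object) {
  cat(sprintf("AssocResults: %d SNPs x %d traits | %d untestable\n",
              nrow(object@beta), ncol(object@beta), sum(object@untestable)))
})

#' @rdname AWMatrix-class
#' @export
setMethod("show", "AWMatrix", function(object) {
  cat(sprintf("AWMatrix: %d genes x %d traits | key trait '%s'\n",
              nrow(object@z), ncol(object@z), object@keyTrait))
})

#' @rdname CoAssocNetwork-class
#' @export
setMethod("show", "CoAssocNetwork", function(object) {
  cat(sprintf("CoAssocNetwork: %d nodes (%d regulators), %d edges\n",
              nrow(object@nodes), sum(object@nodes$isRegulator),
              nrow(object@edges)))
})
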