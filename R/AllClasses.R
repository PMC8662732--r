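#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits
NULL

#' GenotypePanel: additive-dosage genotypes with SNP metadata
#'
#' Individuals x SNPs matrix of counted-allele dosages (0/1/2, `NA` for
#' missing) together with per-SNP metadata: identifier, chromosome, physical
#' position, counted and alternative allele, minor allele frequency and call
#' rate. Unmapped SNPs carry chromosome `"0"` and position 0 (PLINK
#' convention) and are removed by [qcFilter()] when `mappedOnly = TRUE`.
#'
#' @slot dosage numeric matrix, individuals in rows (rownames = sample ids),
#'   SNPs in columns (colnames = SNP ids).
#' @slot snpInfo `data.frame` with columns `snp`, `chrom`, `pos`,
#'   `alleleCounted`, `alleleOther`, `maf`, `callRate`; one row per column of
#'   `dosage`, same order.
#' @name GenotypePanel-class
#' @aliases GenotypePanel-class
#' @exportClass GenotypePanel
setClass("GenotypePanel",
  representation(dosage = "matrix", snpInfo = "data.frame"))

setValidity("GenotypePanel", function(object) {
  msg <- character()
  d <- object@dosage
  si <- object@snpInfo
  if (ncol(d) != nrow(si))
    msg <- c(msg, "ncol(dosage) must equal nrow(snpInfo)")
  need <- c("snp", "chrom", "pos", "alleleCounted", "alleleOther",
            "maf", "callRate")
  if (!all(need %in% names(si)))
    msg <- c(msg, paste("snpInfo missing columns:",
                        paste(setdiff(need, names(si)), collapse = ", ")))
  else {
    if (!is.null(colnames(d)) && !identical(colnames(d), si$snp))
      msg <- c(msg, "colnames(dosage) must match snpInfo$snp")
    if (any(si$maf < 0 | si$maf > 0.5, na.rm = TRUE))
      msg <- c(msg, "MAF must lie in [0, 0.5]")
    if (any(si$callRate < 0 | si$callRate > 1, na.rm = TRUE))
      msg <- c(msg, "call rate must lie in [0, 1]")
    # positions strictly increasing within each mapped chromosome
    mapped <- si$chrom != "0" & !is.na(si$chrom) & si$pos > 0
    for (ch in unique(si$chrom[mapped])) {
      p <- si$pos[mapped & si$chrom == ch]
      if (any(diff(p) <= 0)) {
        msg <- c(msg, sprintf("positions not strictly increasing on chrom %s", ch))
        break
      }
    }
  }
  bad <- d[!is.na(d) & !(d %in% c(0, 1, 2))]
  if (length(bad)) msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' TraitTable: multi-trait phenotypes plus covariate factors
#'
#' @slot traits numeric matrix, individuals x traits (`NA` allowed).
#' @slot covariates `data.frame` with factors `sex` (2 levels), `batch`
#'   and `labBatch`; rownames are sample ids matching `rownames(traits)`.
#' @slot spec per-trait analysis spec: `data.frame` with columns `trait`,
#'   `batchFactor` (`"batch"` or `"labBatch"`) and `logTransform` (logical).
#'   Phagocytosis-type traits use the finer laboratory-batch factor.
#' @name TraitTable-class
#' @exportClass TraitTable
setClass("TraitTable",
  representation(traits = "matrix", covariates = "data.frame",
                 spec = "data.frame"))

setValidity("TraitTable", function(object) {
  msg <- character()
  if (nrow(object@traits) != nrow(object@covariates))
    msg <- c(msg, "traits and covariates must have the same number of rows")
  need <- c("sex", "batch", "labBatch")
  if (!all(need %in% names(object@covariates)))
    msg <- c(msg, "covariates must contain sex, batch and labBatch factors")
  if (!all(c("trait", "batchFactor", "logTransform") %in% names(object@spec)))
    msg <- c(msg, "spec must have columns trait, batchFactor, logTransform")
  else {
    if (!all(colnames(object@traits) %in% object@spec$trait))
      msg <- c(msg, "every trait column needs a spec row")
    if (!all(object@spec$batchFactor %in% c("batch", "labBatch")))
      msg <- c(msg, "batchFactor must be 'batch' or 'labBatch'")
  }
  tv <- object@traits
  if (any(!is.finite(tv[!is.na(tv)])))
    msg <- c(msg, "trait values must be finite where non-missing")
  if (length(msg)) msg else TRUE
})

#' GRM: genomic relationship matrix
#'
#' Allele-frequency-standardized genotype cross-products (Yang et al. / GCTA
#' scaling): off-diagonal \eqn{G_{ij} = m^{-1}\sum_k (x_{ik}-2p_k)(x_{jk}-2p_k)
#' / (2 p_k (1-p_k))} and the dedicated diagonal estimator
#' \eqn{G_{ii} = 1 + m^{-1}\sum_k (x_{ik}^2 - (1+2p_k)x_{ik} + 2p_k^2) /
#' (2 p_k (1-p_k))}.
#'
#' @slot matrix symmetric n x n numeric matrix with sample-id dimnames.
#' @slot nSnpsUsed number of SNPs the matrix was built from.
#' @name GRM-class
#' @exportClass GRM
setClass("GRM", representation(matrix = "matrix", nSnpsUsed = "integer"))

setValidity("GRM", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "GRM must be square")
  else if (max(abs(m - t(m))) > 1e-10) msg <- c(msg, "GRM must be symmetric (1e-10)")
  if (object@nSnpsUsed < 1L) msg <- c(msg, "nSnpsUsed must be positive")
  if (length(msg)) msg else TRUE
})

#' AssocResults: per-(SNP, trait) mixed-model association statistics
#'
#' @slot beta,se,p numeric matrices (SNPs x traits) of allele-substitution
#'   effects, standard errors and two-sided Wald p-values. Untestable SNPs
#'   (zero dosage variance after imputation) carry `NA` in all three and are
#'   flagged in `untestable`, never silently dropped.
#' @slot nUsed integer matrix of per-test sample sizes.
#' @slot untestable logical matrix.
#' @slot snpInfo SNP metadata carried over from the panel.
#' @name AssocResults-class
#' @exportClass AssocResults
setClass("AssocResults",
  representation(beta = "matrix", se = "matrix", p = "matrix",
                 nUsed = "matrix", untestable = "matrix",
                 snpInfo = "data.frame"))

setValidity("AssocResults", function(object) {
  msg <- character()
  dims <- dim(object@beta)
  for (sl in c("se", "p", "nUsed", "untestable"))
    if (!identical(dim(slot(object, sl)), dims))
      msg <- c(msg, sprintf("slot '%s' dimension mismatch", sl))
  pv <- object@p[!is.na(object@p)]
  if (any(pv <= 0 | pv > 1)) msg <- c(msg, "p-values must lie in (0, 1]")
  sev <- object@se[!is.na(object@se)]
  if (any(sev <= 0)) msg <- c(msg, "standard errors must be positive")
  if (length(msg)) msg else TRUE
})

#' AWMatrix: genes x traits association weight matrix
#'
#' Each row is a gene's profile of standardized SNP effects across traits:
#' the raw cell is the signed t-value (beta/se) of the gene's representative
#' SNP for that trait, and columns are standardized to mean 0 / unit sample
#' variance so traits on wildly different measurement scales are comparable.
#'
#' @slot z numeric matrix, genes x traits (rownames gene ids, colnames traits).
#' @slot geneToSnp named character vector: representative SNP per gene row.
#' @slot keyTrait the key phenotype the SNP selection was seeded with.
#' @name AWMatrix-class
#' @exportClass AWMatrix
setClass("AWMatrix",
  representation(z = "matrix", geneToSnp = "character", keyTrait = "character"))

setValidity("AWMatrix", function(object) {
  msg <- character()
  if (nrow(object@z) != length(object@geneToSnp))
    msg <- c(msg, "one representative SNP per gene row required")
  if (nrow(object@z) > 1) {
    mu <- colMeans(object@z)
    v <- apply(object@z, 2, stats::var)
    if (any(abs(mu) > 1e-8)) msg <- c(msg, "columns must be centred (1e-8)")
    if (any(abs(v - 1) > 1e-6)) msg <- c(msg, "columns must have unit variance")
  }
  if (length(msg)) msg else TRUE
})

#' CoAssocNetwork: PCIT-significant gene co-association network
#'
#' Undirected network whose nodes are genes (isolated nodes retained) and
#' whose edges are the gene pairs surviving PCIT, weighted by the Pearson
#' correlation of their AWM effect profiles. Regulator nodes are flagged by
#' case-insensitive symbol match against a regulator census.
#'
#' @slot nodes `data.frame` with columns `gene`, `symbol`, `isRegulator`.
#' @slot edges `data.frame` with columns `from`, `to`, `weight`; each
#'   unordered pair appears once, `from < to`, no self-edges.
#' @name CoAssocNetwork-class
#' @exportClass CoAssocNetwork
setClass("CoAssocNetwork",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("CoAssocNetwork", function(object) {
  msg <- character()
  if (!all(c("gene", "symbol", "isRegulator") %in% names(object@nodes)))
    msg <- c(msg, "nodes need columns gene, symbol, isRegulator")
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e)))
    msg <- c(msg, "edges need columns from, to, weight")
  else if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
    if (!all(e$from %in% object@nodes$gene & e$to %in% object@nodes$gene))
      msg <- c(msg, "edge endpoints must be nodes")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate undirected edges")
  }
  if (length(msg)) msg else TRUE
})
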