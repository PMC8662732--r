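# per-SNP mean imputation of missing dosages (GCTA-style)
meanImpute <- function(x) {
  miss <- is.na(x)
  if (!any(miss)) return(x)
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  x[idx] <- mu[idx[, 2]]
  x
}

# drop SNPs whose counted-allele frequency is 0 or 1 (degenerate for the GRM)
dropMonomorphic <- function(geno) {
  d <- dosages(geno)
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (all(keep)) return(geno)
  subsetSnps(geno, which(keep))
}

#' Subset a genotype panel by SNP index or id
#'
#' @param geno a [GenotypePanel-class].
#' @param snps integer indices or SNP ids.
#' @return a [GenotypePanel-class] restricted to the requested SNPs, in
#'   panel order.
#' @export
subsetSnps <- function(geno, snps) {
  si <- snpInfo(geno)
  idx <- if (is.character(snps)) match(snps, si$snp) else as.integer(snps)
  if (anyNA(idx) || any(idx < 1L | idx > nrow(si)))
    stop("unknown SNP selection")
  idx <- sort(unique(idx))
  methods::new("GenotypePanel",
               dosage = dosages(geno)[, idx, drop = FALSE],
               snpInfo = si[idx, , drop = FALSE])
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# fixed-effect design matrix for one trait: intercept + sex + chosen batch
# factor, reference levels dropped
traitDesign <- function(traitTable, trait) {
  spec <- traitSpec(traitTable)
  row <- spec[spec$trait == trait, ]
  if (nrow(row) != 1L) stop(sprintf("unknown trait '%s'", trait))
  cov <- covariates(traitTable)
  bf <- cov[[row$batchFactor]]
  X <- stats::model.matrix(~ sex + bf, data = data.frame(sex = cov$sex, bf = bf))
  rownames(X) <- rownames(cov)
  X
}

# trait vector with the per-trait log transform applied when flagged
traitVector <- function(traitTable, trait) {
  spec <- traitSpec(traitTable)
  row <- spec[spec$trait == trait, ]
  if (nrow(row) != 1L) stop(sprintf("unknown trait '%s'", trait))
  y <- traitValues(traitTable)[, trait]
  if (isTRUE(row$logTransform)) {
    if (any(y <= 0, na.rm = TRUE))
      stop(sprintf("log transform requested for '%s' but non-positive values present",
                   trait))
    y <- log(y)
  }
  y
}
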