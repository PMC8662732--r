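#' SNP quality control
#'
#' Applies the three panel QC rules in order: (1) minor allele frequency
#' below `mafMin` (computed from non-missing dosages; the boundary itself is
#' retained, i.e. SNPs with MAF >= `mafMin` pass), (2) missingness above
#' `missMax` (inclusive boundary retained), (3) no valid map position
#' (chromosome `"0"`/`NA` or position <= 0). Each removed SNP is attributed
#' to the first rule it fails.
#'
#' @param geno a [GenotypePanel-class].
#' @param mafMin minimum MAF retained (default 0.05).
#' @param missMax maximum missingness retained (default 0.10).
#' @param mappedOnly drop unmapped SNPs (default `TRUE`).
#' @return list with `geno` (filtered panel, MAF/call rate refreshed) and
#'   `report` (`data.frame` of per-rule removal counts plus input/retained
#'   totals).
#' @export
qcFilter <- function(geno, mafMin = 0.05, missMax = 0.10, mappedOnly = TRUE) {
  d <- dosages(geno)
  si <- snpInfo(geno)
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0          # all-missing SNP: treated as MAF 0
  missFrac <- colMeans(is.na(d))
  unmapped <- is.na(si$chrom) | si$chrom == "0" | is.na(si$pos) | si$pos <= 0

  failMaf <- maf < mafMin
  failMiss <- !failMaf & missFrac > missMax
  failMap <- if (mappedOnly) !failMaf & !failMiss & unmapped
             else rep(FALSE, ncol(d))
  keep <- !(failMaf | failMiss | failMap)
  if (!any(keep))
    stop(sprintf(paste0("QC removed every SNP (input %d: %d below MAF %.3g, ",
                        "%d above missingness %.3g, %d unmapped)"),
                 ncol(d), sum(failMaf), mafMin, sum(failMiss), missMax,
                 sum(failMap)))
  report <- data.frame(
    rule = c("input", "maf", "missingness", "unmapped", "retained"),
    count = c(ncol(d), sum(failMaf), sum(failMiss), sum(failMap), sum(keep)),
    stringsAsFactors = FALSE)
  out <- subsetSnps(geno, which(keep))
  # refresh MAF/call-rate metadata on the retained panel
  so <- snpInfo(out)
  po <- colMeans(dosages(out), na.rm = TRUE) / 2
  so$maf <- pmin(po, 1 - po)
  so$callRate <- colMeans(!is.na(dosages(out)))
  out@snpInfo <- so
  list(geno = out, report = report)
}
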