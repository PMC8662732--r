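#' Random-subset heritability validation
#'
#' Mirrors the selected-SNP heritability check: per trait, estimate `h2`
#' using (a) a GRM built from a focal SNP subset, (b) the whole-panel GRM,
#' and (c) `nIter` random same-size subsets drawn from the panel, then rank
#' the focal subset's estimate among the random iterates (rank 1 = the
#' focal estimate exceeds every random one).
#'
#' @param geno QC-passed [GenotypePanel-class].
#' @param traitTable matching [TraitTable-class].
#' @param subsetIds character vector of focal SNP ids (must be in the
#'   panel; at most the panel size).
#' @param nIter number of random iterations (default 100).
#' @param seed integer seed for the random subsets.
#' @param traits optional character subset of traits.
#' @return list with `perTrait` (`data.frame`: `trait`, `h2Subset`,
#'   `h2Whole`, `nRandomBelow`, `rank`, `maxRandom`) and `randomH2`
#'   (`nIter` x traits matrix).
#' @export
subsetH2Validation <- function(geno, traitTable, subsetIds, nIter = 100L,
                               seed = 1L, traits = NULL) {
  si <- snpInfo(geno)
  if (length(subsetIds) > nrow(si))
    stop("subset larger than the panel")
  if (!all(subsetIds %in% si$snp)) stop("subset contains unknown SNP ids")
  if (is.null(traits)) traits <- colnames(traitValues(traitTable))
  set.seed(seed)
  draws <- replicate(nIter, sample(si$snp, length(subsetIds)),
                     simplify = FALSE)

  h2ForPanel <- function(panel) {
    eg <- eigen(grmMatrix(buildGRM(panel)), symmetric = TRUE)
    vapply(traits, function(tr) {
      y <- traitVector(traitTable, tr)
      X <- traitDesign(traitTable, tr)
      remlH2(y, X, eg)$h2
    }, numeric(1))
  }
  h2Sub <- h2ForPanel(subsetSnps(geno, subsetIds))
  h2Whole <- h2ForPanel(geno)
  vals <- vapply(draws, function(ids) h2ForPanel(subsetSnps(geno, ids)),
                 numeric(length(traits)))
  randomH2 <- if (length(traits) == 1L) matrix(vals, ncol = 1L) else t(vals)
  colnames(randomH2) <- traits
  perTrait <- data.frame(
    trait = traits,
    h2Subset = h2Sub, h2Whole = h2Whole,
    nRandomBelow = colSums(randomH2 < rep(h2Sub, each = nIter)),
    rank = 1L + colSums(randomH2 >= rep(h2Sub, each = nIter)),
    maxRandom = apply(randomH2, 2, max),
    stringsAsFactors = FALSE, row.names = NULL)
  list(perTrait = perTrait, randomH2 = randomH2)
}
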