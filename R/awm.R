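#' Key-phenotype and pleiotropy SNP selection
#'
#' Selects (1) SNPs nominally associated with the key phenotype
#' (`p < alpha`, strict) and (2) pleiotropic SNPs associated with at least
#' `minTraits` of the analysed traits (the key trait counts among them),
#' and merges the two lists. P-values are deliberately nominal: the AWM
#' design trades stringency for information, recovering signal that a
#' genome-wide correction would discard.
#'
#' @param assoc an [AssocResults-class].
#' @param keyTrait key phenotype name (must be an `assoc` column).
#' @param alpha nominal significance threshold (default 0.05, strict `<`).
#' @param minTraits pleiotropy threshold (default 3).
#' @return list with `keyTraitSnps`, `pleiotropicSnps`, `merged` (character
#'   vectors, panel order) and `perSnp` (`data.frame`: `snp`,
#'   `nAssocTraits`, `assocTraits` comma-joined, `inKey`, `inPleio`).
#' @export
selectSnps <- function(assoc, keyTrait, alpha = 0.05, minTraits = 3L) {
  p <- assocP(assoc)
  if (!keyTrait %in% colnames(p))
    stop(sprintf("unknown key trait '%s'", keyTrait))
  hit <- !is.na(p) & p < alpha
  nAssoc <- as.integer(rowSums(hit))
  inKey <- hit[, keyTrait]
  inPleio <- nAssoc >= minTraits
  snps <- rownames(p)
  perSnp <- data.frame(
    snp = snps, nAssocTraits = nAssoc,
    assocTraits = apply(hit, 1L, function(h)
      paste(colnames(p)[h], collapse = ",")),
    inKey = inKey, inPleio = inPleio,
    stringsAsFactors = FALSE, row.names = NULL)
  list(keyTraitSnps = snps[inKey],
       pleiotropicSnps = snps[inPleio],
       merged = snps[inKey | inPleio],
       perSnp = perSnp)
}

#' Annotate selected SNPs to genes within a window
#'
#' A pair (SNP, gene) is kept iff the chromosomes match and the SNP
#' position lies in `[start - window, end + window]` (both boundaries
#' inclusive; strand is ignored, the window is symmetric). A SNP may map
#' to more than one gene; SNPs with no gene are dropped and counted.
#' Overlap is computed with [GenomicRanges::findOverlaps()] on the
#' window-extended gene ranges.
#'
#' @param snps `data.frame` with columns `snp`, `chrom`, `pos` (e.g. the
#'   `snpInfo` rows of the selected SNPs).
#' @param genes gene annotation `data.frame` (`geneId`, `symbol`, `chrom`,
#'   `start`, `end`, ...), 1-based closed coordinates.
#' @param window symmetric window in bp (default 5000); must be >= 0.
#' @return list with `pairs` (`data.frame`: `snp`, `geneId`, `symbol`,
#'   `chrom`, `pos`) and `nUnannotated` (SNPs mapping to no gene).
#' @export
annotateSnps <- function(snps, genes, window = 5000L) {
  if (window < 0) stop("window must be non-negative")
  if (!nrow(snps)) return(list(pairs = data.frame(), nUnannotated = 0L))
  snpGr <- GenomicRanges::GRanges(snps$chrom,
                                  IRanges::IRanges(snps$pos, snps$pos))
  geneGr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start - as.integer(window)),
                     genes$end + as.integer(window)))
  ov <- GenomicRanges::findOverlaps(snpGr, geneGr)
  qi <- S4Vectors::queryHits(ov); sj <- S4Vectors::subjectHits(ov)
  pairs <- data.frame(snp = snps$snp[qi], geneId = genes$geneId[sj],
                      symbol = genes$symbol[sj], chrom = snps$chrom[qi],
                      pos = snps$pos[qi], stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$geneId, pairs$snp), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       nUnannotated = nrow(snps) - length(unique(qi)))
}

#' Build the association weight matrix
#'
#' One row per annotated gene, one column per trait. The raw cell is the
#' signed t-value (`beta/se`) of the gene's representative SNP for that
#' trait (t-values, not raw effects, because the traits live on wildly
#' different measurement scales); columns are then standardized to mean 0
#' and unit sample variance. The representative SNP per gene is chosen by
#' `perGeneRule`:
#' \describe{
#'   \item{`"most_pleiotropic"`}{most associated traits (`p < alpha`),
#'     ties broken by smaller key-trait p-value, then smaller genomic
#'     position.}
#'   \item{`"min_key_p"`}{smallest key-trait p-value, ties by position.}
#' }
#' Genes sharing a SNP each receive that SNP's row.
#'
#' @param assoc an [AssocResults-class] covering every paired SNP.
#' @param pairs (SNP, gene) pairs from [annotateSnps()].
#' @param keyTrait key phenotype name.
#' @param perGeneRule representative-SNP rule (see above).
#' @param alpha threshold used to count associated traits (default 0.05).
#' @return an [AWMatrix-class].
#' @export
buildAWM <- function(assoc, pairs, keyTrait, perGeneRule = "most_pleiotropic",
                     alpha = 0.05) {
  perGeneRule <- match.arg(perGeneRule, c("most_pleiotropic", "min_key_p"))
  p <- assocP(assoc)
  if (!keyTrait %in% colnames(p)) stop(sprintf("unknown key trait '%s'", keyTrait))
  if (!all(pairs$snp %in% rownames(p)))
    stop("pairs reference SNPs absent from the association results")
  nAssoc <- rowSums(!is.na(p) & p < alpha)
  keyP <- p[, keyTrait]
  si <- snpInfo(assoc)
  pos <- si$pos[match(rownames(p), si$snp)]
  names(pos) <- rownames(p)

  pickSnp <- function(cand) {
    if (length(cand) == 1L) return(cand)
    keyp <- keyP[cand]; keyp[is.na(keyp)] <- Inf
    o <- if (perGeneRule == "most_pleiotropic")
      order(-nAssoc[cand], keyp, pos[cand], cand)
    else order(keyp, pos[cand], cand)
    cand[o[1L]]
  }
  geneIds <- sort(unique(pairs$geneId))
  repSnp <- vapply(geneIds,
                   function(g) pickSnp(unique(pairs$snp[pairs$geneId == g])),
                   character(1))
  tmat <- assocBeta(assoc)[repSnp, , drop = FALSE] /
    assocSE(assoc)[repSnp, , drop = FALSE]
  rownames(tmat) <- geneIds
  v <- apply(tmat, 2, stats::var)
  if (any(!is.finite(v)) || any(v < 1e-12))
    stop("constant or non-finite AWM column(s): ",
         paste(colnames(tmat)[!is.finite(v) | v < 1e-12], collapse = ", "))
  z <- scale(tmat)            # sample SD, mean 0 / unit variance per column
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  methods::new("AWMatrix", z = z, geneToSnp = repSnp, keyTrait = keyTrait)
}

#' Trait relationships from the AWM columns
#'
#' Pearson correlations between AWM trait columns, agglomerative
#' hierarchical clustering on the distance `1 - r` with average linkage,
#' and the dendrogram serialized as a Newick string (via [ape::as.phylo()]).
#'
#' @param awm an [AWMatrix-class] with at least 3 gene rows.
#' @param k optional number of clusters to cut at.
#' @return list with `correlation` (traits x traits), `hclust`, `newick`
#'   (character), `clusters` (named integer vector if `k` given).
#' @export
traitRelationships <- function(awm, k = NULL) {
  z <- awmValues(awm)
  if (nrow(z) < 3L) stop("need at least 3 genes")
  if (ncol(z) < 2L) stop("need at least 2 traits")
  r <- stats::cor(z)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(correlation = r, hclust = hc, newick = newick, clusters = clusters)
}
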