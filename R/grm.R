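#' Build the genomic relationship matrix
#'
#' Yang et al. / GCTA estimator over a QC-passed panel. With `x_ik` the
#' (mean-imputed) counted-allele dosage and `p_k` the counted-allele sample
#' frequency:
#' \deqn{G_{ij} = \frac{1}{m}\sum_k \frac{(x_{ik}-2p_k)(x_{jk}-2p_k)}
#'   {2p_k(1-p_k)}, \quad i \ne j}
#' \deqn{G_{ii} = 1 + \frac{1}{m}\sum_k \frac{x_{ik}^2-(1+2p_k)x_{ik}+2p_k^2}
#'   {2p_k(1-p_k)}}
#' The diagonal uses the dedicated less-biased estimator rather than the
#' plain squared standardized dosage.
#'
#' @param geno a [GenotypePanel-class]; missing dosages are mean-imputed per
#'   SNP before use. Monomorphic SNPs (sample frequency 0 or 1) are an
#'   error: they must have been removed by [qcFilter()].
#' @return a [GRM-class].
#' @export
buildGRM <- function(geno) {
  x <- meanImpute(dosages(geno))
  m <- ncol(x)
  p <- colMeans(x) / 2
  if (any(p <= 0 | p >= 1))
    stop(sum(p <= 0 | p >= 1),
         " monomorphic SNP(s) in the panel; run qcFilter() first")
  denom <- 2 * p * (1 - p)
  z <- sweep(x, 2, 2 * p) / rep(sqrt(denom), each = nrow(x))
  G <- tcrossprod(z) / m
  # diagonal: 1 + (1/m) sum_k (x^2 - (1+2p)x + 2p^2) / (2pq)
  num <- x^2 - sweep(x, 2, 1 + 2 * p, FUN = "*") +
    matrix(2 * p^2, nrow(x), m, byrow = TRUE)
  diag(G) <- 1 + rowSums(sweep(num, 2, denom, FUN = "/")) / m
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(x), rownames(x))
  methods::new("GRM", matrix = G, nSnpsUsed = as.integer(m))
}
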