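#' Mixed linear model association scan for one trait
#'
#' EMMAX/P3D-style scan: the variance components are estimated once under
#' the no-SNP model ([remlH2()]) and the resulting covariance
#' `V = sigma_u^2 G + sigma_e^2 I` is held fixed while each SNP's dosage is
#' tested as a fixed covariate by generalized least squares in the GRM
#' eigenbasis. The Wald statistic `(a_l / se)^2 ~ chi^2(1)` gives a
#' two-sided p-value. SNP missing dosages are mean-imputed; SNPs with zero
#' dosage variance after imputation are flagged untestable (`NA`
#' statistics), never dropped.
#'
#' @param geno a [GenotypePanel-class] (QC-passed).
#' @param y numeric trait vector, one value per panel individual (`NA`
#'   allowed; complete cases are used and reported in `nUsed`).
#' @param X fixed-effect design matrix (no SNP column).
#' @param grm [GRM-class] / matrix / eigen result over the panel
#'   individuals.
#' @param vc variance components from [remlH2()] on the same trait; if
#'   `NULL` they are estimated here.
#' @return `data.frame` with one row per SNP: `snp`, `chrom`, `pos`,
#'   `beta`, `se`, `p`, `nUsed`, `untestable`.
#' @export
mlmAssoc <- function(geno, y, X, grm, vc = NULL) {
  X <- as.matrix(X)
  ok <- !is.na(y) & stats::complete.cases(X)
  S <- meanImpute(dosages(geno))
  si <- snpInfo(geno)
  if (!all(ok)) {
    G <- if (is(grm, "GRM")) grmMatrix(grm)
         else if (is.matrix(grm)) grm
         else grm$vectors %*% (grm$values * t(grm$vectors))
    grm <- G[ok, ok, drop = FALSE]
    y <- y[ok]; X <- X[ok, , drop = FALSE]; S <- S[ok, , drop = FALSE]
  }
  if (is.null(vc)) vc <- remlH2(y, X, grm)
  eg <- grmEigen(grm)
  # absolute-scale weights: Var(rotated residual)_i = sigma2u*lambda_i + sigma2e
  w <- vc$sigma2u * eg$values + vc$sigma2e
  w <- pmax(w, 1e-12)
  sw <- sqrt(w)
  ys <- drop(crossprod(eg$vectors, y)) / sw
  Xs <- crossprod(eg$vectors, X) / sw
  Ss <- crossprod(eg$vectors, S) / sw
  qrX <- qr(Xs)
  yr <- qr.resid(qrX, ys)
  Sr <- qr.resid(qrX, Ss)
  ss <- colSums(Sr^2)
  untestable <- ss < 1e-10
  beta <- se <- p <- rep(NA_real_, ncol(S))
  beta[!untestable] <- colSums(Sr[, !untestable, drop = FALSE] * yr) /
    ss[!untestable]
  se[!untestable] <- sqrt(1 / ss[!untestable])
  chi2 <- (beta / se)^2
  p[!untestable] <- stats::pchisq(chi2[!untestable], df = 1,
                                  lower.tail = FALSE)
  p[!is.na(p) & p == 0] <- .Machine$double.xmin  # keep p in (0, 1]
  data.frame(snp = si$snp, chrom = si$chrom, pos = si$pos,
             beta = beta, se = se, p = p,
             nUsed = length(y), untestable = untestable,
             stringsAsFactors = FALSE)
}

#' GWAS over every trait of a study
#'
#' Runs [remlH2()] and [mlmAssoc()] per trait, applying each trait's
#' covariate spec (sex plus 6-level batch, or the 12-level lab batch for
#' phagocytosis-type traits; optional natural-log transform). The GRM
#' eigendecomposition is computed once and reused for all traits with
#' identical complete-case sets.
#'
#' @param geno QC-passed [GenotypePanel-class].
#' @param traitTable a [TraitTable-class] over the same individuals, same
#'   order.
#' @param grm [GRM-class] built from `geno` (or a compatible matrix).
#' @param traits optional character subset of traits.
#' @return list with `assoc` (an [AssocResults-class]) and `h2`
#'   (`data.frame`: `trait`, `h2`, `se`, `loglik`, `n`, `boundary`).
#' @export
gwasAllTraits <- function(geno, traitTable, grm, traits = NULL) {
  if (is.null(traits)) traits <- colnames(traitValues(traitTable))
  stopifnot(all(traits %in% colnames(traitValues(traitTable))))
  if (!identical(sampleIds(geno), sampleIds(traitTable)))
    stop("genotype and trait tables must cover the same individuals in order")
  si <- snpInfo(geno)
  m <- ncol(dosages(geno)); nT <- length(traits)
  empty <- function() matrix(NA_real_, m, nT, dimnames = list(si$snp, traits))
  beta <- empty(); se <- empty(); p <- empty()
  nUsed <- matrix(NA_integer_, m, nT, dimnames = list(si$snp, traits))
  unte <- matrix(FALSE, m, nT, dimnames = list(si$snp, traits))
  h2tab <- data.frame(trait = traits, h2 = NA_real_, se = NA_real_,
                      loglik = NA_real_, n = NA_integer_, boundary = NA,
                      stringsAsFactors = FALSE)
  Gfull <- grmMatrix(if (is(grm, "GRM")) grm else
                     methods::new("GRM", matrix = as.matrix(grm),
                                  nSnpsUsed = 1L))
  egCache <- list()
  for (k in seq_along(traits)) {
    tr <- traits[k]
    y <- traitVector(traitTable, tr)
    X <- traitDesign(traitTable, tr)
    ok <- !is.na(y) & stats::complete.cases(X)
    key <- paste(which(ok), collapse = ",")
    if (is.null(egCache[[key]]))
      egCache[[key]] <- eigen(Gfull[ok, ok, drop = FALSE], symmetric = TRUE)
    eg <- egCache[[key]]
    # drop unused factor columns so the design stays full rank on the subset
    Xok <- X[ok, , drop = FALSE]
    Xok <- Xok[, qr(Xok)$pivot[seq_len(qr(Xok)$rank)], drop = FALSE]
    vc <- remlH2(y[ok], Xok, eg)
    h2tab$h2[k] <- vc$h2; h2tab$se[k] <- vc$h2se
    h2tab$loglik[k] <- vc$loglik; h2tab$n[k] <- vc$n
    h2tab$boundary[k] <- vc$boundary
    genoOk <- methods::new("GenotypePanel",
                           dosage = dosages(geno)[ok, , drop = FALSE],
                           snpInfo = si)
    res <- mlmAssoc(genoOk, y[ok], Xok, eg, vc)
    beta[, k] <- res$beta; se[, k] <- res$se; p[, k] <- res$p
    nUsed[, k] <- res$nUsed; unte[, k] <- res$untestable
  }
  assoc <- methods::new("AssocResults", beta = beta, se = se, p = p,
                        nUsed = nUsed, untestable = unte, snpInfo = si)
  list(assoc = assoc, h2 = h2tab)
}
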