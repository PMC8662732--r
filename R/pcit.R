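#' Gene-gene correlations of AWM effect profiles
#'
#' Pearson correlation of every pair of gene rows across traits. Constant
#' rows (zero variance across traits) cannot be correlated; they are
#' excluded and reported.
#'
#' @param awm an [AWMatrix-class] (or plain genes x traits matrix) with at
#'   least 3 trait columns.
#' @return list with `r` (genes x genes correlation matrix, unit diagonal)
#'   and `excluded` (ids of constant rows).
#' @export
geneCorrelations <- function(awm) {
  z <- if (is(awm, "AWMatrix")) awmValues(awm) else as.matrix(awm)
  if (ncol(z) < 3L) stop("need at least 3 trait columns")
  v <- apply(z, 1L, stats::var)
  excluded <- rownames(z)[v < 1e-12]
  z <- z[v >= 1e-12, , drop = FALSE]
  r <- stats::cor(t(z))
  diag(r) <- 1
  list(r = r, excluded = excluded)
}

# shared trio rules ----------------------------------------------------------
# For a trio (x, y, z) with direct correlations r_xy, r_xz, r_yz the three
# first-order partials are
#   r_xy.z = (r_xy - r_xz r_yz) / sqrt((1-r_xz^2)(1-r_yz^2))  (and rotations)
# the trio tolerance is
#   eps = (|r_xy.z/r_xy| + |r_xz.y/r_xz| + |r_yz.x/r_yz|) / 3
# and the trio REJECTS edge (x, y) iff |r_xy| <= |eps r_xz| AND
# |r_xy| <= |eps r_yz|. A trio with any |direct| < 1e-12 or a non-positive
# partial denominator is skipped: an undefined tolerance cannot reject.

#' Hand-evaluable PCIT trio quantities
#'
#' Computes the three first-order partial correlations and the trio
#' tolerance for a single trio of direct correlations.
#'
#' @param rxy,rxz,ryz direct Pearson correlations.
#' @return list with `partials` (`rxy.z`, `rxz.y`, `ryz.x`), `eps`, and
#'   `skip` (TRUE when the trio is degenerate and cannot reject).
#' @export
pcitTrio <- function(rxy, rxz, ryz) {
  d1 <- (1 - rxz^2) * (1 - ryz^2)
  d2 <- (1 - rxy^2) * (1 - ryz^2)
  d3 <- (1 - rxy^2) * (1 - rxz^2)
  if (min(abs(c(rxy, rxz, ryz))) < 1e-12 || min(d1, d2, d3) <= 0)
    return(list(partials = c(rxy.z = NA, rxz.y = NA, ryz.x = NA),
                eps = NA_real_, skip = TRUE))
  pxy <- (rxy - rxz * ryz) / sqrt(d1)
  pxz <- (rxz - rxy * ryz) / sqrt(d2)
  pyz <- (ryz - rxy * rxz) / sqrt(d3)
  eps <- (abs(pxy / rxy) + abs(pxz / rxz) + abs(pyz / ryz)) / 3
  list(partials = c(rxy.z = pxy, rxz.y = pxz, ryz.x = pyz),
       eps = eps, skip = FALSE)
}

#' PCIT edge significance (fast path)
#'
#' Partial Correlation and Information Theory network filter: an edge
#' (x, y) is significant iff no third node z rejects it under the trio
#' rule above. The implementation loops over the conditioning node z and
#' evaluates all (x, y) pairs against it with vectorized matrix algebra,
#' giving O(n) passes of O(n^2) work; it is exactly equivalent to the
#' literal triple loop ([pcitBruteforce()]).
#'
#' @param corr symmetric correlation matrix (e.g. `geneCorrelations()$r`),
#'   n >= 3.
#' @param maxN guard on the O(n^3) trio scan; raise explicitly for larger
#'   problems (default 5000).
#' @return logical n x n symmetric matrix, `TRUE` for significant edges,
#'   `FALSE` diagonal.
#' @export
pcit <- function(corr, maxN = 5000L) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (n != ncol(corr) || max(abs(corr - t(corr))) > 1e-8)
    stop("correlation matrix must be square and symmetric")
  if (n > maxN)
    stop("n = ", n, " exceeds maxN = ", maxN,
         "; the O(n^3) trio scan must be enabled explicitly")
  if (n < 3L) stop("PCIT needs at least 3 nodes")
  R <- corr; diag(R) <- 1
  absR <- abs(R)
  sig <- matrix(TRUE, n, n)
  oneM <- 1 - R^2                      # 1 - r^2, pairwise
  for (z in seq_len(n)) {
    rz <- R[, z]
    oz <- 1 - rz^2
    # partials for every (x, y) against conditioning node z:
    d1 <- outer(oz, oz)                #   denom^2 of r_xy.z
    d2 <- outer(rep(1, n), oz) * oneM  #   denom^2 of r_xz.y : (1-r_xy^2)(1-r_yz^2)
    d3 <- outer(oz, rep(1, n)) * oneM  #   denom^2 of r_yz.x : (1-r_xy^2)(1-r_xz^2)
    p1 <- (R - outer(rz, rz)) / sqrt(pmax(d1, 1e-300))
    p2 <- (outer(rz, rep(1, n)) - R * outer(rep(1, n), rz)) /
      sqrt(pmax(d2, 1e-300))
    p3 <- (outer(rep(1, n), rz) - R * outer(rz, rep(1, n))) /
      sqrt(pmax(d3, 1e-300))
    aXZ <- outer(absR[, z], rep(1, n)) # |r_xz| as (x, y) matrix
    aYZ <- t(aXZ)                      # |r_yz|
    eps <- (abs(p1) / pmax(absR, 1e-300) + abs(p2) / pmax(aXZ, 1e-300) +
            abs(p3) / pmax(aYZ, 1e-300)) / 3
    usable <- absR >= 1e-12 & aXZ >= 1e-12 & aYZ >= 1e-12 &
      d1 > 0 & d2 > 0 & d3 > 0
    rej <- usable & (absR <= eps * aXZ) & (absR <= eps * aYZ)
    rej[z, ] <- FALSE; rej[, z] <- FALSE   # z must differ from x and y
    sig <- sig & !rej
  }
  sig <- sig & absR >= 1e-12           # a zero correlation is no association
  diag(sig) <- FALSE
  dimnames(sig) <- dimnames(corr)
  sig
}

#' PCIT edge significance (literal triple-loop reference)
#'
#' O(n^3) scalar implementation of exactly the same trio rules, kept as an
#' independent reference for the vectorized path. Warns above `sizeBound`
#' nodes.
#'
#' @param corr symmetric correlation matrix.
#' @param sizeBound soft size limit (default 200).
#' @return logical significance matrix as in [pcit()].
#' @export
pcitBruteforce <- function(corr, sizeBound = 200L) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (n != ncol(corr) || max(abs(corr - t(corr))) > 1e-8)
    stop("correlation matrix must be square and symmetric")
  if (n < 3L) stop("PCIT needs at least 3 nodes")
  if (n > sizeBound)
    warning("pcitBruteforce is O(n^3); n = ", n, " will be slow")
  R <- corr; diag(R) <- 1
  sig <- matrix(TRUE, n, n); diag(sig) <- FALSE
  for (x in seq_len(n - 1L)) for (y in (x + 1L):n) {
    if (abs(R[x, y]) < 1e-12) {        # a zero correlation is no association
      sig[x, y] <- sig[y, x] <- FALSE
      next
    }
    for (z in seq_len(n)) {
      if (z == x || z == y) next
      tr <- pcitTrio(R[x, y], R[x, z], R[y, z])
      if (tr$skip) next
      if (abs(R[x, y]) <= tr$eps * abs(R[x, z]) &&
          abs(R[x, y]) <= tr$eps * abs(R[y, z])) {
        sig[x, y] <- sig[y, x] <- FALSE
        break
      }
    }
  }
  dimnames(sig) <- dimnames(corr)
  sig
}
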