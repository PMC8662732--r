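# Rotate (y, X) into the GRM eigenbasis. 'grm' may be a GRM object, a plain
# symmetric matrix, or a precomputed eigen() result (list with values/vectors).
grmEigen <- function(grm) {
  if (is(grm, "GRM")) grm <- grmMatrix(grm)
  if (is.list(grm) && !is.null(grm$values)) return(grm)
  eigen(grm, symmetric = TRUE)
}

# restricted log-likelihood of y = Xb + u + e profiled over (b, sigma2) at a
# given h2, in the eigenrotated basis; constants independent of h2 dropped
remlLoglikRotated <- function(ys, Xs, lambda, h2) {
  n <- length(ys); p <- ncol(Xs)
  w <- h2 * lambda + (1 - h2)
  if (any(w <= 0)) return(-1e300)   # infeasible h2 (negative eigenvalue tail)
  sw <- sqrt(w)
  Xw <- Xs / sw
  yw <- ys / sw
  qrX <- qr(Xw)
  if (qrX$rank < p) return(-1e300)
  res <- qr.resid(qrX, yw)
  rss <- sum(res^2)
  if (rss < 1e-12 * max(1, sum(yw^2)))
    stop("zero residual variance: trait is an exact linear function of the covariates")
  s2 <- rss / (n - p)
  R <- qr.R(qrX)
  logdetXWX <- 2 * sum(log(abs(diag(R))))
  -0.5 * ((n - p) * log(s2) + sum(log(w)) + logdetXWX + (n - p))
}

#' Profile restricted log-likelihood over heritability
#'
#' Evaluates the REML log-likelihood of the single-random-effect model
#' `y = Xb + u + e`, `u ~ N(0, G sigma_u^2)`, profiled over the fixed
#' effects and the total variance, at each requested `h2`. Used to verify
#' that [remlH2()] returns the maximiser.
#'
#' @param y numeric trait vector (complete cases only).
#' @param X fixed-effect design matrix.
#' @param grm [GRM-class], matrix, or precomputed `eigen()` result.
#' @param h2 vector of heritabilities in (0, 1).
#' @return numeric vector of profile restricted log-likelihoods (additive
#'   constants dropped; comparable across `h2`, not across models).
#' @export
remlProfileLoglik <- function(y, X, grm, h2) {
  eg <- grmEigen(grm)
  ys <- drop(crossprod(eg$vectors, y))
  Xs <- crossprod(eg$vectors, X)
  vapply(h2, function(h) remlLoglikRotated(ys, Xs, eg$values, h), numeric(1))
}

#' REML variance components and heritability
#'
#' Maximises the restricted likelihood of `y = Xb + u + e` with
#' `u ~ N(0, G sigma_u^2)` via one eigendecomposition of the GRM and a
#' one-dimensional profile optimisation over `h2` in `[1e-6, 1-1e-6]`
#' (coarse grid scan followed by golden-section refinement, so the global
#' profile optimum is bracketed). The standard error of `h2` comes from the
#' numerical curvature of the profile restricted log-likelihood at the
#' optimum; with a single random effect the profile is exact, so no AI-REML
#' iteration is needed.
#'
#' @param y numeric trait vector; individuals with missing `y` or
#'   covariates are dropped (complete-case analysis).
#' @param X fixed-effect design matrix (same rows as `y`); must be full
#'   rank after dropping incomplete rows.
#' @param grm [GRM-class] (or matrix / eigen result) over the same
#'   individuals, in the same order.
#' @return list with `sigma2u`, `sigma2e`, `h2`, `h2se` (`NA` at a
#'   boundary), `loglik`, `n`, `boundary` flag.
#' @export
remlH2 <- function(y, X, grm) {
  X <- as.matrix(X)
  ok <- !is.na(y) & stats::complete.cases(X)
  if (!all(ok)) {
    G <- if (is(grm, "GRM")) grmMatrix(grm)
         else if (is.matrix(grm)) grm
         else grm$vectors %*% (grm$values * t(grm$vectors))
    grm <- G[ok, ok, drop = FALSE]
    y <- y[ok]; X <- X[ok, , drop = FALSE]
  }
  n <- length(y); p <- qr(X)$rank
  if (p < ncol(X)) stop("rank-deficient fixed-effect design")
  if (n < ncol(X) + 2L)
    stop("need at least ", ncol(X) + 2L, " complete observations")
  eg <- grmEigen(grm)
  ys <- drop(crossprod(eg$vectors, y))
  Xs <- crossprod(eg$vectors, X)
  ll <- function(h) remlLoglikRotated(ys, Xs, eg$values, h)
  lo <- 1e-6; hi <- 1 - 1e-6
  grid <- seq(lo, hi, length.out = 41L)
  lg <- vapply(grid, ll, numeric(1))
  if (all(lg <= -1e299)) stop("REML profile likelihood not finite anywhere")
  i <- which.max(lg)
  bl <- grid[max(1L, i - 1L)]; bu <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(ll, lower = bl, upper = bu, maximum = TRUE,
                         tol = 1e-9)
  h2 <- opt$maximum; l0 <- opt$objective
  # the optimize() bracket can clip a boundary optimum; check the edges
  if (lg[1] >= l0) { h2 <- lo; l0 <- lg[1] }
  if (lg[length(lg)] >= l0) { h2 <- hi; l0 <- lg[length(lg)] }
  boundary <- h2 <= lo + 1e-5 || h2 >= hi - 1e-5
  h2se <- NA_real_
  if (!boundary) {
    d <- min(1e-4, (h2 - lo) / 2, (hi - h2) / 2)
    curv <- (ll(h2 + d) - 2 * l0 + ll(h2 - d)) / d^2
    if (is.finite(curv) && curv < 0) h2se <- sqrt(-1 / curv)
  }
  # total variance at the optimum
  w <- h2 * eg$values + (1 - h2)
  sw <- sqrt(w)
  qrX <- qr(Xs / sw)
  rss <- sum(qr.resid(qrX, ys / sw)^2)
  s2 <- rss / (n - ncol(X))
  list(sigma2u = h2 * s2, sigma2e = (1 - h2) * s2, h2 = h2, h2se = h2se,
       loglik = l0, n = n, boundary = boundary)
}
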