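# independent REML oracle: direct 2-parameter optimisation of the dense
# restricted likelihood, no eigen trick, no profiling
directRemlH2 <- function(y, X, G) {
  n <- length(y)
  nll <- function(par) {
    V <- exp(par[1]) * G + exp(par[2]) * diag(n)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(1e10)
    Vi <- chol2inv(cV)
    XtVX <- crossprod(X, Vi %*% X)
    b <- solve(XtVX, crossprod(X, Vi %*% y))
    r <- y - X %*% b
    as.numeric(sum(log(diag(cV))) +
               0.5 * determinant(XtVX)$modulus +
               0.5 * crossprod(r, Vi %*% r))
  }
  opt <- stats::optim(c(0, 0), nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  su <- exp(opt$par[1]); se <- exp(opt$par[2])
  su / (su + se)
}

sharedPanel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tinySimConfig(seed = 31, nIndividuals = 600L, nSnps = 800L,
                           nChromosomes = 4L, switchProb = 1,
                           nSires = 10L, nDams = 60L,
                           missingRate = 0, badSnpFraction = 0,
                           unmappedRate = 0, mafRange = c(0.1, 0.5))
      geno <- qcFilter(simulateGenotypes(cfg)$geno)$geno
      eg <- eigen(grmMatrix(buildGRM(geno)), symmetric = TRUE)
      cache <<- list(geno = geno, eg = eg)
    }
    cache
  }
})

test_that("profile REML agrees with a direct dense REML oracle", {
  set.seed(41)
  n <- 80
  cfg <- tinySimConfig(seed = 41, nIndividuals = n, nSnps = 300L)
  G <- grmMatrix(buildGRM(qcFilter(simulateGenotypes(cfg)$geno)$geno))
  eg <- eigen(G, symmetric = TRUE)
  X <- cbind(1, rnorm(n))
  for (rep in 1:3) {
    u <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(n))
    y <- drop(scale(u)) + rnorm(n) + X %*% c(1, 0.5)
    fit <- remlH2(y, X, G)
    h2o <- directRemlH2(y, X, G)
    expect_lt(abs(fit$h2 - h2o), 2e-3)
  }
})

test_that("the returned h2 maximises the profile restricted likelihood", {
  sp <- sharedPanel()
  n <- length(sp$eg$values)
  set.seed(43)
  for (rep in 1:5) {
    u <- sp$eg$vectors %*% (sqrt(pmax(sp$eg$values, 0)) * rnorm(n))
    y <- sqrt(0.4) * drop(scale(u)) + sqrt(0.6) * rnorm(n)
    fit <- remlH2(y, matrix(1, n, 1), sp$eg)
    probe <- unique(pmin(pmax(fit$h2 + c(-0.01, 0.01), 1e-6), 1 - 1e-6))
    ll <- remlProfileLoglik(y, matrix(1, n, 1), sp$eg, probe)
    expect_true(all(ll <= fit$loglik + 1e-8))
  }
})

test_that("a null trait on a proper GRM yields near-zero heritability", {
  sp <- sharedPanel()
  n <- length(sp$eg$values)
  set.seed(47)
  h2s <- vapply(1:20, function(s) {
    y <- rnorm(n)                     # sigma_u^2 = 0 by construction
    remlH2(y, matrix(1, n, 1), sp$eg)$h2
  }, numeric(1))
  expect_gte(sum(h2s < 0.05), 18)
})

test_that("an exactly-deterministic trait errors instead of estimating", {
  sp <- sharedPanel()
  n <- length(sp$eg$values)
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(2, 1))            # no noise at all
  expect_error(remlH2(y, X, sp$eg), "residual variance")
  expect_error(remlH2(rnorm(n), cbind(1, 1), sp$eg), "rank-deficient")
  expect_error(remlH2(rnorm(3), cbind(1, c(0, 1, 2)), diag(3)),
               "observations")
})

test_that("with an identity GRM and zero genetic variance the scan is OLS", {
  set.seed(53)
  n <- 60
  d <- matrix(rbinom(n * 20, 2, 0.4), n, 20,
              dimnames = list(sprintf("i%02d", 1:n), sprintf("s%02d", 1:20)))
  si <- data.frame(snp = colnames(d), chrom = "1", pos = 1:20 * 100L,
                   alleleCounted = "B", alleleOther = "A", maf = 0.4,
                   callRate = 1, stringsAsFactors = FALSE)
  pan <- methods::new("GenotypePanel", dosage = d, snpInfo = si)
  y <- rnorm(n); X <- cbind(1, rnorm(n))
  vc <- list(sigma2u = 0, sigma2e = 1, h2 = 0)
  res <- mlmAssoc(pan, y, X, diag(n), vc)
  ols <- vapply(seq_len(20), function(j)
    coef(lm(y ~ X[, 2] + d[, j]))[3], numeric(1))
  expect_lt(max(abs(res$beta - ols)), 1e-8)
})

test_that("null SNP tests are calibrated and uniform", {
  ps <- list()
  for (s in 1:3) {
    cfg <- tinySimConfig(seed = 60 + s, nIndividuals = 250L, nSnps = 1000L,
                         nChromosomes = 4L, switchProb = 1, missingRate = 0,
                         badSnpFraction = 0, unmappedRate = 0,
                         mafRange = c(0.1, 0.5))
    geno <- qcFilter(simulateGenotypes(cfg)$geno)$geno
    eg <- eigen(grmMatrix(buildGRM(geno)), symmetric = TRUE)
    n <- nrow(dosages(geno))
    set.seed(70 + s)
    u <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(n))
    y <- sqrt(0.3) * drop(scale(u)) + sqrt(0.7) * rnorm(n)
    vc <- remlH2(y, matrix(1, n, 1), eg)
    res <- mlmAssoc(geno, y, matrix(1, n, 1), eg, vc)
    ps[[s]] <- res$p[!res$untestable]
  }
  pooled <- unlist(ps)
  frac <- mean(pooled < 0.05)
  expect_gte(frac, 0.035); expect_lte(frac, 0.065)
  ksPass <- vapply(ps, function(p)
    suppressWarnings(ks.test(p, "punif")$p.value) > 0.01, logical(1))
  expect_gte(sum(ksPass), 2)          # majority of seeds
})

test_that("a planted causal SNP is detected with overwhelming evidence", {
  sp <- sharedPanel()
  geno <- sp$geno
  n <- nrow(dosages(geno))
  set.seed(81)
  hits <- vapply(1:20, function(s) {
    j <- sample(ncol(dosages(geno)), 1)
    x <- dosages(geno)[, j]
    y <- 0.5 * drop(scale(x)) + rnorm(n)
    vc <- remlH2(y, matrix(1, n, 1), sp$eg)
    res <- mlmAssoc(geno, y, matrix(1, n, 1), sp$eg, vc)
    res$p[j] < 1e-6
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("zero-variance SNPs are flagged untestable, never dropped", {
  n <- 40
  d <- cbind(s1 = rep(1, n), s2 = rbinom(n, 2, 0.5))
  rownames(d) <- sprintf("i%02d", 1:n)
  si <- data.frame(snp = colnames(d), chrom = "1", pos = c(100L, 200L),
                   alleleCounted = "B", alleleOther = "A", maf = c(0.5, 0.4),
                   callRate = 1, stringsAsFactors = FALSE)
  pan <- methods::new("GenotypePanel", dosage = d, snpInfo = si)
  res <- mlmAssoc(pan, rnorm(n), matrix(1, n, 1), diag(n),
                  list(sigma2u = 0, sigma2e = 1, h2 = 0))
  expect_identical(res$untestable, c(TRUE, FALSE))
  expect_true(is.na(res$p[1]) && !is.na(res$p[2]))
  expect_identical(nrow(res), 2L)
})

test_that("subset-h2 validation identities and determinism hold", {
  cfg <- tinySimConfig(seed = 91, nIndividuals = 60L, nSnps = 200L)
  sim <- simulateGenotypes(cfg)
  ts <- simulateTraits(sim, cfg)
  geno <- qcFilter(sim$geno)$geno
  allIds <- snpInfo(geno)$snp
  v <- subsetH2Validation(geno, ts$traits, allIds, nIter = 1, seed = 5,
                          traits = "gdT")
  expect_identical(v$perTrait$h2Subset, v$perTrait$h2Whole)
  v2 <- subsetH2Validation(geno, ts$traits, allIds[1:50], nIter = 1, seed = 5,
                           traits = "gdT")
  v3 <- subsetH2Validation(geno, ts$traits, allIds[1:50], nIter = 1, seed = 5,
                           traits = "gdT")
  expect_identical(v2$randomH2, v3$randomH2)
  expect_error(subsetH2Validation(geno, ts$traits,
                                  c(allIds[1:10], "nope"), 1, 1),
               "unknown")
  expect_error(subsetH2Validation(geno, ts$traits, rep(allIds, 2), 1, 1),
               "larger")
})
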