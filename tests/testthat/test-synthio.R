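test_that("genotype simulation is deterministic and well-coded", {
  cfg <- tinySimConfig(seed = 11)
  a <- simulateGenotypes(cfg)
  b <- simulateGenotypes(cfg)
  expect_identical(dosages(a$geno), dosages(b$geno))
  expect_identical(a$genes, b$genes)
  expect_identical(a$pedigree, b$pedigree)
  d <- dosages(a$geno)
  expect_true(all(d[!is.na(d)] %in% 0:2))
  si <- snpInfo(a$geno)
  expect_true(all(si$maf >= 0 & si$maf <= 0.5, na.rm = TRUE))
  # positions strictly increasing within mapped chromosomes
  for (ch in setdiff(unique(si$chrom), "0"))
    expect_true(all(diff(si$pos[si$chrom == ch]) > 0))
})

test_that("traits are deterministic and respect degenerate heritability", {
  cfg <- tinySimConfig(seed = 3, h2Targets = c(A = 0, B = 0.5, gdT = 0.4,
                                               C = 0.3, D = 0.2, E = 0.6))
  sim <- simulateGenotypes(cfg)
  t1 <- simulateTraits(sim, cfg)
  t2 <- simulateTraits(sim, cfg)
  expect_identical(traitValues(t1$traits), traitValues(t2$traits))
  # h2 target 0 => generating genetic variance exactly 0
  expect_identical(unname(t1$truth$trueH2["A"]), 0)
  # realized generating h2 tracks the targets
  expect_lt(max(abs(t1$truth$trueH2 - cfg$h2Targets)), 0.05)
})

test_that("haplotype copying induces adjacent-SNP LD beyond independence", {
  # switch probability 0: gametes copy whole founder haplotypes; adjacent
  # SNPs share templates and must correlate more than independent draws
  mkCor <- function(switchProb, seed) {
    cfg <- tinySimConfig(seed = seed, nSnps = 1200L, nChromosomes = 1L,
                         switchProb = switchProb, missingRate = 0,
                         badSnpFraction = 0, unmappedRate = 0)
    d <- dosages(simulateGenotypes(cfg)$geno)
    keep <- apply(d, 2, sd) > 0
    d <- d[, keep]
    n <- min(2000L, ncol(d) - 1L)
    mean(vapply(seq_len(n), function(j)
      abs(cor(d[, j], d[, j + 1L])), numeric(1)), na.rm = TRUE)
  }
  ldMax <- mkCor(0, 21)
  ldNone <- mkCor(1, 22)     # switch every SNP: templates independent
  # the baseline is nonzero (family relatedness inflates all pairwise
  # correlations); whole-haplotype copying must clearly exceed it
  expect_gt(ldMax, ldNone + 0.02)
})

test_that("without planted fixed effects, sexes differ only by sampling noise", {
  cfg <- tinySimConfig(seed = 5, nIndividuals = 800L, nSnps = 300L,
                       sexEffectSd = 0, batchEffectSd = 0,
                       missingRate = 0, badSnpFraction = 0, unmappedRate = 0)
  sim <- simulateGenotypes(cfg)
  grm <- buildGRM(qcFilter(sim$geno)$geno)
  ps <- vapply(1:20, function(s) {
    cfg2 <- cfg; cfg2$seed <- cfg$seed + s * 10L
    ts <- simulateTraits(sim, cfg2, grm = grm)
    y <- traitValues(ts$traits)[, "gdT"]
    sex <- covariates(ts$traits)$sex
    t.test(y[sex == "M"], y[sex == "F"])$p.value
  }, numeric(1))
  expect_gt(median(ps), 0.01)
})

test_that("orthogonal module loadings decorrelate cross-module effect profiles", {
  mp <- simulateModuleProfiles(nTraits = 30, nModules = 11,
                               genesPerModule = 4, moduleCor = 0.8, seed = 8)
  R <- cor(t(mp$profiles))
  cross <- abs(R[outer(mp$membership, mp$membership, "!=")])
  expect_lt(mean(cross), 0.15)
  within <- R[outer(mp$membership, mp$membership, "==") & upper.tri(R)]
  expect_gt(mean(within), 0.6)
})

test_that("every planted causal SNP is recoverable by the annotation rule", {
  cfg <- tinySimConfig(seed = 13)
  sim <- simulateGenotypes(cfg)
  ts <- simulateTraits(sim, cfg)
  si <- snpInfo(sim$geno)
  causal <- ts$truth$causalMap
  ann <- annotateSnps(si[match(causal$snp, si$snp), c("snp", "chrom", "pos")],
                      sim$genes, window = 5000)
  hit <- paste(ann$pairs$snp, ann$pairs$geneId)
  expect_true(all(paste(causal$snp, causal$gene) %in% hit))
})

test_that("infeasible configurations are rejected", {
  expect_error(tinySimConfig(nSnps = 10L), "anchor")
  expect_error(tinySimConfig(mafRange = c(0, 0.5)), "mafRange")
  expect_error(tinySimConfig(h2Targets = rep(0.99, 6)), "0.95")
  expect_error(tinySimConfig(h2Targets = c(0.1, 0.2)), "one value per trait")
})
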