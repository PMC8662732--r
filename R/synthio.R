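#' Default trait panel: 30 health-related phenotypes
#'
#' Trait names and default heritability targets for the simulated study
#' population: immunological, haematological and stress phenotypes with
#' narrow-sense heritabilities spanning roughly 0.1--0.6. Phagocytosis-type
#' traits (names containing `PHAGO`) are tagged to use the finer 12-level
#' laboratory-batch factor, two lab batches nested in each of the 6 rearing
#' batches.
#'
#' @return named numeric vector of per-trait heritability targets.
#' @export
defaultTraitPanel <- function() {
  c(HCT = 0.338, HB = 0.371, ERY = 0.532, MCV = 0.588, MCH = 0.560,
    MCHC = 0.503, PLA = 0.449, LEU = 0.226, EO = 0.345, LYM = 0.314,
    MON = 0.076, NEU = 0.299, IgAsal = 0.188, IgA = 0.497, IgG = 0.593,
    IgM = 0.399, CRP = 0.180, HP = 0.285, NO = 0.278, gdT = 0.439,
    PHAGO_PC = 0.284, GRANU_PHAGO_PC = 0.285, MON_PHAGO_PC = 0.368,
    LYM_PHAGO_PC = 0.531, PHAGO_FITC = 0.406, GRANU_PHAGO_FITC = 0.416,
    MON_PHAGO_FITC = 0.308, LYM_PHAGO_FITC = 0.379, CORT = 0.209,
    NLR = 0.466)
}

#' Simulation configuration
#'
#' Defines a synthetic study: a genotyped population with LD, sparse
#' pleiotropic causal SNPs organised into co-effect modules anchored to
#' genes (one designated regulator hub per module), a polygenic background
#' drawn with covariance proportional to the realised GRM, and sex/batch
#' fixed effects. Defaults emulate the scale of a commercial pig
#' immunocompetence study: 432 individuals, 68,516 array SNPs of which
#' roughly 42k survive QC (planted low-MAF, high-missingness and unmapped
#' fractions), 30 traits, 6 batches.
#'
#' @param nIndividuals,nSnps,nChromosomes population and panel size.
#' @param mafRange range the per-SNP counted-allele frequency is drawn from
#'   (uniform); must lie within (0, 0.5].
#' @param nTraits number of traits. If 30 (default), the named panel from
#'   [defaultTraitPanel()] is used.
#' @param h2Targets per-trait heritability targets in `[0, 0.95]`.
#' @param nModules,genesPerModule,hubExtraTargets co-effect module layout:
#'   each module has `genesPerModule` core genes plus `hubExtraTargets`
#'   extra member genes wired to it; one core gene per module is the
#'   designated regulator hub.
#' @param moduleCor target pairwise correlation of causal-effect vectors
#'   within a module (shared latent trait-loading construction).
#' @param causalFraction fraction of each trait's genetic variance carried
#'   by the planted causal SNPs (the rest is GRM-covariant polygenic).
#' @param effectProfileSd overall scale of causal effect profiles.
#' @param sexEffectSd,batchEffectSd SD of per-trait sex and batch effects
#'   (trait-SD units).
#' @param batchLevels,labBatchLevels rearing-batch and laboratory-batch
#'   factor sizes (`labBatchLevels` must be `2 * batchLevels`).
#' @param missingRate MCAR genotype missingness; `badSnpFraction` of SNPs
#'   get elevated missingness `badSnpMissingRate` so the QC missingness
#'   rule has real work to do.
#' @param badSnpFraction,badSnpMissingRate see `missingRate`.
#' @param unmappedRate fraction of SNPs flagged as not mapped (chrom "0").
#' @param switchProb haplotype-copying switch probability per SNP; 0 gives
#'   maximal adjacent-SNP LD, 1 gives independent SNPs.
#' @param nHaplotypes size of the founder haplotype pool per chromosome.
#' @param nSires,nDams parents behind the full-sib litter structure (each
#'   dam is one litter; defaults scale the 22-boar / 132-sow / 134-litter
#'   layout with the population size).
#' @param recombRate per-SNP meiotic recombination probability.
#' @param geneHalfWidth half-span of simulated genes in bp (default 15000,
#'   i.e. 30 kb genes, the mammalian average); genes are anchored on a SNP.
#' @param nBackgroundGenes genes with no planted effect (annotation decoys).
#' @param nDecoyRegulators background genes added to the regulator census.
#' @param censusExtra census symbols absent from the annotation.
#' @param seed integer root seed (< 2^31 - 10).
#' @return a validated list of class `simConfig`.
#' @export
simConfig <- function(nIndividuals = 432L, nSnps = 68516L,
                      nChromosomes = 18L, mafRange = c(0.01, 0.5),
                      nTraits = 30L, h2Targets = NULL,
                      nModules = 15L, genesPerModule = 20L,
                      hubExtraTargets = 15L, moduleCor = 0.8,
                      causalFraction = 0.5, effectProfileSd = 1,
                      sexEffectSd = 0.25, batchEffectSd = 0.25,
                      batchLevels = 6L, labBatchLevels = 2L * batchLevels,
                      missingRate = 0.02, badSnpFraction = 0.05,
                      badSnpMissingRate = 0.20, unmappedRate = 0.30,
                      switchProb = 0.10, nHaplotypes = 24L,
                      nSires = max(2L, round(nIndividuals / 20)),
                      nDams = max(2L, round(nIndividuals / 3.3)),
                      recombRate = 0.005, geneHalfWidth = 15000L,
                      nBackgroundGenes = nModules * genesPerModule,
                      nDecoyRegulators = 10L, censusExtra = 5L,
                      seed = 1L) {
  if (is.null(h2Targets)) {
    h2Targets <- if (nTraits == 30L) defaultTraitPanel() else {
      h <- seq(0.2, 0.8, length.out = nTraits)
      names(h) <- sprintf("T%02d", seq_len(nTraits))
      h
    }
  }
  if (is.null(names(h2Targets)))
    names(h2Targets) <- sprintf("T%02d", seq_along(h2Targets))
  cfg <- list(nIndividuals = as.integer(nIndividuals),
              nSnps = as.integer(nSnps),
              nChromosomes = as.integer(nChromosomes),
              mafRange = as.numeric(mafRange),
              nTraits = as.integer(nTraits), h2Targets = h2Targets,
              nModules = as.integer(nModules),
              genesPerModule = as.integer(genesPerModule),
              hubExtraTargets = as.integer(hubExtraTargets),
              moduleCor = moduleCor, causalFraction = causalFraction,
              effectProfileSd = effectProfileSd,
              sexEffectSd = sexEffectSd, batchEffectSd = batchEffectSd,
              batchLevels = as.integer(batchLevels),
              labBatchLevels = as.integer(labBatchLevels),
              missingRate = missingRate,
              badSnpFraction = badSnpFraction,
              badSnpMissingRate = badSnpMissingRate,
              unmappedRate = unmappedRate, switchProb = switchProb,
              nHaplotypes = as.integer(nHaplotypes),
              nSires = as.integer(nSires), nDams = as.integer(nDams),
              recombRate = recombRate,
              geneHalfWidth = as.integer(geneHalfWidth),
              nBackgroundGenes = as.integer(nBackgroundGenes),
              nDecoyRegulators = as.integer(nDecoyRegulators),
              censusExtra = as.integer(censusExtra),
              seed = as.integer(seed))
  class(cfg) <- "simConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  counts <- c("nIndividuals", "nSnps", "nChromosomes", "nTraits",
              "nModules", "genesPerModule", "batchLevels",
              "labBatchLevels", "nHaplotypes", "nSires", "nDams")
  for (f in counts)
    if (cfg[[f]] <= 0L) stop(sprintf("'%s' must be a positive count", f))
  if (cfg$hubExtraTargets < 0L || cfg$nBackgroundGenes < 0L)
    stop("hubExtraTargets and nBackgroundGenes must be non-negative")
  if (cfg$mafRange[1] <= 0 || cfg$mafRange[2] > 0.5 ||
      cfg$mafRange[1] > cfg$mafRange[2])
    stop("mafRange must lie within (0, 0.5] with lo <= hi")
  if (length(cfg$h2Targets) != cfg$nTraits)
    stop("h2Targets must have one value per trait")
  if (any(cfg$h2Targets < 0 | cfg$h2Targets > 0.95))
    stop("h2Targets must lie in [0, 0.95]")
  if (cfg$moduleCor < 0 || cfg$moduleCor >= 1)
    stop("moduleCor must lie in [0, 1)")
  if (cfg$causalFraction < 0 || cfg$causalFraction > 1)
    stop("causalFraction must lie in [0, 1]")
  for (f in c("missingRate", "badSnpFraction", "badSnpMissingRate",
              "unmappedRate", "switchProb", "recombRate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", f))
  if (cfg$missingRate > 0.05)
    stop("baseline missingRate must not exceed 5%")
  nModGenes <- cfg$nModules * (cfg$genesPerModule + cfg$hubExtraTargets)
  if (cfg$nSnps < nModGenes + cfg$nBackgroundGenes)
    stop("nSnps too small to place one anchor SNP per gene ",
         "(need >= nModules*(genesPerModule+hubExtraTargets)+nBackgroundGenes)")
  if (cfg$geneHalfWidth < 0L) stop("geneHalfWidth must be non-negative")
  if (cfg$seed >= 2^31 - 10) stop("seed must be below 2^31 - 10")
  invisible(TRUE)
}

# last-observation-carried-forward over switch points: values 'new' are
# adopted where 'sw' is TRUE and carried forward elsewhere
locfSwitch <- function(new, sw) {
  sw[1] <- TRUE
  new[sw][cumsum(sw)]
}

#' Simulate a genotype panel with LD, litters, gene annotation and modules
#'
#' Per-SNP counted-allele frequencies are drawn uniformly from `mafRange`.
#' The population has a two-tier structure emulating a commercial nucleus:
#' founder haplotypes -> parents (each parental gamete copies segments from
#' the founder pool, switching templates with probability `switchProb` per
#' SNP, which induces adjacent-SNP LD) -> full-sib litters (each offspring
#' gamete is a meiotic recombination of its parent's two gametes at
#' `recombRate` per SNP). Litter mates therefore share roughly half their
#' genome, giving the GRM the family structure that carries most of the
#' heritability information at a few hundred individuals. Genes are placed
#' as 4 kb intervals anchored on distinct mapped SNPs; module genes' anchor
#' SNPs are the planted causal SNPs (every causal SNP therefore lies inside
#' its gene, well within the +/-5 kb annotation window). Planted QC
#' failures: low-MAF SNPs (from the low end of `mafRange`), a
#' `badSnpFraction` of SNPs with elevated missingness, and an
#' `unmappedRate` fraction with no map position.
#'
#' @param config a [simConfig()].
#' @return list with components `geno` ([GenotypePanel-class]), `genes`
#'   (gene annotation `data.frame`: `geneId`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`, `module`, `isHub`, `anchorSnp`), `census` (character
#'   vector of regulator symbols) and `pedigree` (`data.frame`: `id`,
#'   `sire`, `dam`).
#' @export
simulateGenotypes <- function(config) {
  validateSimConfig(config)
  set.seed(config$seed)
  n <- config$nIndividuals; m <- config$nSnps
  nModGenes <- config$nModules * (config$genesPerModule + config$hubExtraTargets)
  nGenes <- nModGenes + config$nBackgroundGenes

  # panel layout: SNPs spread over chromosomes, sorted positions
  chromOf <- sort(rep_len(seq_len(config$nChromosomes), m))
  pos <- integer(m)
  spacing <- 50000L
  for (ch in seq_len(config$nChromosomes)) {
    idx <- which(chromOf == ch)
    pos[idx] <- sort(sample.int(length(idx) * spacing, length(idx))) + 10000L
  }
  p <- stats::runif(m, config$mafRange[1], config$mafRange[2])

  # gene anchors: distinct SNPs, kept mapped and at comfortable MAF so the
  # planted causal signal survives QC
  anchorIdx <- sort(sample.int(m, nGenes))
  p[anchorIdx] <- stats::runif(nGenes, max(0.10, config$mafRange[1]),
                               config$mafRange[2])

  # pedigree: full-sib litters, one dam per litter, sires over several dams
  nS <- config$nSires; nD <- config$nDams
  dam <- sample(rep_len(seq_len(nD), n))
  sireOfDam <- sample.int(nS, nD, replace = TRUE)
  sire <- sireOfDam[dam]

  # founder pool -> parental gametes -> offspring meiosis, per chromosome
  dosage <- matrix(0L, n, m)
  H <- config$nHaplotypes
  for (ch in seq_len(config$nChromosomes)) {
    idx <- which(chromOf == ch)
    mc <- length(idx)
    pool <- matrix(stats::rbinom(H * mc, 1L, rep(p[idx], each = H)), H, mc)
    nPar <- nS + nD                        # sires first, then dams
    parGam <- matrix(0L, 2L * nPar, mc)
    for (g in seq_len(2L * nPar)) {
      sw <- stats::runif(mc) < config$switchProb
      tpl <- locfSwitch(sample.int(H, mc, replace = TRUE), sw)
      parGam[g, ] <- pool[cbind(tpl, seq_len(mc))]
    }
    meiosis <- function(parent) {          # recombine the parent's 2 gametes
      sw <- stats::runif(mc) < config$recombRate
      tpl <- locfSwitch(sample.int(2L, mc, replace = TRUE), sw)
      parGam[cbind(2L * (parent - 1L) + tpl, seq_len(mc))]
    }
    for (i in seq_len(n))
      dosage[i, idx] <- meiosis(sire[i]) + meiosis(nS + dam[i])
  }

  # planted missingness (MCAR baseline + a bad-SNP stratum), anchors spared
  storage.mode(dosage) <- "double"
  if (config$missingRate > 0)
    dosage[stats::runif(length(dosage)) < config$missingRate] <- NA
  nonAnchor <- setdiff(seq_len(m), anchorIdx)
  if (config$badSnpFraction > 0 && length(nonAnchor)) {
    bad <- sample(nonAnchor, round(config$badSnpFraction * m))
    for (j in bad)
      dosage[stats::runif(n) < config$badSnpMissingRate, j] <- NA
  }

  # unmapped stratum (chrom "0", pos 0), anchors spared
  chrom <- as.character(chromOf)
  if (config$unmappedRate > 0 && length(nonAnchor)) {
    unm <- sample(nonAnchor, round(config$unmappedRate * m))
    chrom[unm] <- "0"; pos[unm] <- 0L
  }

  snpIds <- sprintf("SNP%06d", seq_len(m))
  sampIds <- sprintf("IND%04d", seq_len(n))
  dimnames(dosage) <- list(sampIds, snpIds)
  freqNonMiss <- colMeans(dosage, na.rm = TRUE) / 2
  si <- data.frame(snp = snpIds, chrom = chrom, pos = pos,
                   alleleCounted = "B", alleleOther = "A",
                   maf = pmin(freqNonMiss, 1 - freqNonMiss),
                   callRate = colMeans(!is.na(dosage)),
                   stringsAsFactors = FALSE)
  geno <- methods::new("GenotypePanel", dosage = dosage, snpInfo = si)

  # gene table: module genes first (core genes then hub extras), background last
  modSize <- config$genesPerModule + config$hubExtraTargets
  module <- c(rep(seq_len(config$nModules), each = modSize),
              rep(0L, config$nBackgroundGenes))
  isHub <- logical(nGenes)
  isHub[(seq_len(config$nModules) - 1L) * modSize + 1L] <- TRUE
  half <- config$geneHalfWidth
  genes <- data.frame(
    geneId = sprintf("GENE%04d", seq_len(nGenes)),
    symbol = ifelse(isHub,
                    sprintf("TFHUB%02d", cumsum(isHub)),
                    sprintf("G%04d", seq_len(nGenes))),
    chrom = chrom[anchorIdx],
    start = pmax(1L, pos[anchorIdx] - half),
    end = pos[anchorIdx] + half,
    strand = sample(c("+", "-"), nGenes, replace = TRUE),
    module = module, isHub = isHub,
    anchorSnp = snpIds[anchorIdx],
    stringsAsFactors = FALSE)

  census <- genes$symbol[genes$isHub]
  bg <- which(genes$module == 0L)
  if (config$nDecoyRegulators > 0 && length(bg))
    census <- c(census,
                genes$symbol[sample(bg, min(config$nDecoyRegulators, length(bg)))])
  if (config$censusExtra > 0)
    census <- c(census, sprintf("TFABSENT%02d", seq_len(config$censusExtra)))
  list(geno = geno, genes = genes, census = sort(census),
       pedigree = data.frame(id = sampIds, sire = sire, dam = dam,
                             stringsAsFactors = FALSE))
}

#' Simulate correlated multi-trait phenotypes with known ground truth
#'
#' Inverts the analysis model: each trait is sex effect + batch effect +
#' causal genetic value + GRM-covariant polygenic value + residual. Module
#' k has a latent trait-loading vector; each member gene's causal-effect
#' vector is `sqrt(moduleCor) * loading + sqrt(1-moduleCor) * perturbation`,
#' so effect profiles within a module correlate at about `moduleCor` while
#' cross-module profiles are uncorrelated. Genetic and residual components
#' are empirically standardized so the realised narrow-sense heritability
#' equals the per-trait target; `causalFraction` of the genetic variance
#' comes from the planted causal SNPs and the rest from a polygenic draw
#' with covariance proportional to the realised GRM.
#'
#' @param sim result of [simulateGenotypes()].
#' @param config the same [simConfig()]; only its seed need differ to draw
#'   replicate trait sets on a fixed panel.
#' @param grm optional precomputed [GRM-class] (or eigen decomposition of
#'   one) for the polygenic draw; computed from `sim` when missing.
#' @return list with `traits` ([TraitTable-class]) and `truth` (list:
#'   `causalMap` data.frame, `effects` genes x traits causal-effect matrix,
#'   `hubGenes`, `trueH2`, `fixedEffects`, `moduleLoadings`).
#' @export
simulateTraits <- function(sim, config, grm = NULL) {
  validateSimConfig(config)
  if (any(config$h2Targets >= 1))
    stop("requested heritability >= 1 is infeasible")
  set.seed(config$seed + 1L)
  geno <- sim$geno; genes <- sim$genes
  n <- nrow(dosages(geno))
  traits <- names(config$h2Targets)
  nT <- config$nTraits

  modGenes <- genes[genes$module > 0L, , drop = FALSE]
  nC <- nrow(modGenes)

  # latent loadings and per-gene causal effect vectors
  L <- matrix(stats::rnorm(config$nModules * nT), config$nModules, nT)
  B <- matrix(0, nC, nT, dimnames = list(modGenes$geneId, traits))
  if (nC) {
    pert <- matrix(stats::rnorm(nC * nT), nC, nT)
    B <- (sqrt(config$moduleCor) * L[modGenes$module, , drop = FALSE] +
          sqrt(1 - config$moduleCor) * pert) * config$effectProfileSd
    dimnames(B) <- list(modGenes$geneId, traits)
  }

  # centred, imputed causal dosages
  Xc <- dosages(geno)[, modGenes$anchorSnp, drop = FALSE]
  Xc <- meanImpute(Xc)
  Xc <- sweep(Xc, 2, colMeans(Xc))
  causalVal <- if (nC) Xc %*% B else matrix(0, n, nT)

  # polygenic values with covariance proportional to the realised GRM
  eg <- if (is.null(grm)) eigen(grmMatrix(buildGRM(dropMonomorphic(geno))),
                                symmetric = TRUE)
        else grmEigen(grm)
  sql <- sqrt(pmax(eg$values, 0))
  polyVal <- eg$vectors %*% (sql * matrix(stats::rnorm(n * nT), n, nT))

  # fixed effects
  sex <- factor(sample(c("F", "M"), n, replace = TRUE))
  batch <- factor(sample(seq_len(config$batchLevels), n, replace = TRUE))
  labBatch <- factor(paste0(as.character(batch), "_",
                            sample(1:2, n, replace = TRUE)))
  sexEff <- stats::rnorm(nT, 0, config$sexEffectSd)
  batchEff <- matrix(stats::rnorm(config$batchLevels * nT, 0,
                                  config$batchEffectSd),
                     config$batchLevels, nT)
  labEff <- matrix(stats::rnorm(nlevels(labBatch) * nT, 0,
                                config$batchEffectSd),
                   nlevels(labBatch), nT)

  usesLab <- grepl("PHAGO", traits)
  Y <- matrix(NA_real_, n, nT, dimnames = list(sampleIds(geno), traits))
  trueH2 <- numeric(nT); names(trueH2) <- traits
  std <- function(v) if (stats::sd(v) < 1e-12) v * 0 else
    (v - mean(v)) / stats::sd(v)
  for (t in seq_len(nT)) {
    h2 <- config$h2Targets[t]
    g <- if (h2 == 0) numeric(n) else {
      cpart <- std(causalVal[, t])
      f <- if (all(cpart == 0)) 0 else config$causalFraction
      sqrt(h2) * (sqrt(f) * cpart + sqrt(1 - f) * std(polyVal[, t]))
    }
    e <- sqrt(1 - h2) * std(stats::rnorm(n))
    vg <- stats::var(g); ve <- stats::var(e)
    trueH2[t] <- if (vg + ve == 0) 0 else vg / (vg + ve)
    fb <- if (usesLab[t]) labEff[as.integer(labBatch), t]
          else batchEff[as.integer(batch), t]
    Y[, t] <- g + e + sexEff[t] * (sex == "M") + fb
  }

  cov <- data.frame(sex = sex, batch = batch, labBatch = labBatch,
                    row.names = sampleIds(geno))
  spec <- data.frame(trait = traits,
                     batchFactor = ifelse(usesLab, "labBatch", "batch"),
                     logTransform = FALSE, stringsAsFactors = FALSE)
  tt <- methods::new("TraitTable", traits = Y, covariates = cov, spec = spec)

  truth <- list(
    causalMap = data.frame(module = modGenes$module, gene = modGenes$geneId,
                           snp = modGenes$anchorSnp, isHub = modGenes$isHub,
                           stringsAsFactors = FALSE),
    effects = B,
    hubGenes = modGenes$geneId[modGenes$isHub],
    trueH2 = trueH2,
    fixedEffects = list(sex = sexEff, batch = batchEff, labBatch = labEff),
    moduleLoadings = L)
  list(traits = tt, truth = truth)
}

#' Planted co-effect profile matrix (genes x traits)
#'
#' Directly builds the standardized-effect profiles the genotype/trait
#' simulator plants, without simulating genotypes: module genes share a
#' latent loading (pairwise correlation about `moduleCor`), background
#' genes are pure noise. Used to study network-inference behaviour under a
#' known modular truth.
#'
#' @param nTraits,nModules,genesPerModule,hubExtraTargets,moduleCor,
#'   nBackground as in [simConfig()].
#' @param orthogonal orthogonalise the module loading vectors (Gram-Schmidt
#'   on the random loadings) so cross-module effect profiles are
#'   uncorrelated in expectation -- the "background about zero" planted
#'   condition. Default `TRUE`.
#' @param seed integer seed.
#' @return list: `profiles` (matrix), `membership` (module id per gene, 0 =
#'   background), `hubs` (gene ids, first gene of each module).
#' @export
simulateModuleProfiles <- function(nTraits = 30L, nModules = 3L,
                                   genesPerModule = 20L,
                                   hubExtraTargets = 0L, moduleCor = 0.8,
                                   nBackground = 0L, orthogonal = TRUE,
                                   seed = 1L) {
  set.seed(seed)
  modSize <- genesPerModule + hubExtraTargets
  nG <- nModules * modSize + nBackground
  membership <- c(rep(seq_len(nModules), each = modSize), rep(0L, nBackground))
  L <- matrix(stats::rnorm(nModules * nTraits), nModules, nTraits)
  if (orthogonal && nModules > 1L) {
    L <- t(qr.Q(qr(t(L))))            # orthonormal rows
    L <- L * sqrt(nTraits)            # keep per-element variance about 1
  }
  P <- matrix(stats::rnorm(nG * nTraits), nG, nTraits)
  inMod <- membership > 0L
  P[inMod, ] <- sqrt(moduleCor) * L[membership[inMod], , drop = FALSE] +
    sqrt(1 - moduleCor) * P[inMod, , drop = FALSE]
  rownames(P) <- sprintf("GENE%04d", seq_len(nG))
  colnames(P) <- sprintf("T%02d", seq_len(nTraits))
  hubs <- rownames(P)[(seq_len(nModules) - 1L) * modSize + 1L]
  list(profiles = P, membership = membership, hubs = hubs)
}
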