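#' Pipeline run configuration
#'
#' Assembles and defaults the single configuration object driving
#' [runPipeline()]. Exactly one of `simulate` (a [simConfig()]) or
#' `inputs` (paths: `raw`, `map`, `pheno`, `annotation`, `census`) must be
#' given. Defaults encode the canonical AWM analysis choices: nominal
#' `alpha` 0.05, pleiotropy threshold 3 traits, +/-5 kb annotation window,
#' 100 random-subset validation iterations.
#'
#' @param keyTrait key phenotype name.
#' @param simulate optional [simConfig()].
#' @param inputs optional named list of input paths.
#' @param alpha,minTraits,window,perGeneRule selection/annotation/AWM
#'   parameters (see [selectSnps()], [annotateSnps()], [buildAWM()]).
#' @param mafMin,missMax QC thresholds (see [qcFilter()]).
#' @param pcitMaxN size guard for the PCIT trio scan.
#' @param topK,k,countMode regulator-trio parameters (see [rankTrios()],
#'   [selectKeyRegulators()]).
#' @param validateH2 run the random-subset heritability validation.
#' @param nIter validation iterations (default 100).
#' @param outDir output directory.
#' @param seed root seed; every stochastic stage derives its stream from it.
#' @param force overwrite existing outputs.
#' @return list of class `awmRunConfig`.
#' @export
pipelineConfig <- function(keyTrait = "gdT", simulate = NULL, inputs = NULL,
                           alpha = 0.05, minTraits = 3L, window = 5000L,
                           perGeneRule = "most_pleiotropic",
                           mafMin = 0.05, missMax = 0.10,
                           pcitMaxN = 5000L, topK = 10L, k = 5L,
                           countMode = "targets", validateH2 = FALSE,
                           nIter = 100L, outDir = tempfile("awmnet_run_"),
                           seed = 1L, force = FALSE) {
  cfg <- list(keyTrait = keyTrait, simulate = simulate, inputs = inputs,
              alpha = alpha, minTraits = as.integer(minTraits),
              window = as.integer(window), perGeneRule = perGeneRule,
              mafMin = mafMin, missMax = missMax,
              pcitMaxN = as.integer(pcitMaxN), topK = as.integer(topK),
              k = as.integer(k), countMode = countMode,
              validateH2 = isTRUE(validateH2), nIter = as.integer(nIter),
              outDir = outDir, seed = as.integer(seed), force = isTRUE(force))
  class(cfg) <- "awmRunConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks structural and range constraints and (where resolvable without
#' running anything) name resolution, returning every violation at once
#' rather than failing on the first.
#'
#' @param config an `awmRunConfig` from [pipelineConfig()].
#' @return character vector of violations (empty when the config is valid).
#' @export
validateConfig <- function(config) {
  v <- character()
  hasSim <- !is.null(config$simulate)
  hasInp <- !is.null(config$inputs)
  if (hasSim == hasInp)
    v <- c(v, "exactly one of 'simulate' or 'inputs' must be given")
  if (hasSim) {
    ok <- tryCatch({ validateSimConfig(config$simulate); TRUE },
                   error = function(e) { v <<- c(v, conditionMessage(e)); FALSE })
    if (ok && !config$keyTrait %in% names(config$simulate$h2Targets))
      v <- c(v, sprintf("keyTrait '%s' is not a simulated trait",
                        config$keyTrait))
  }
  if (hasInp) {
    need <- c("raw", "map", "pheno", "annotation", "census")
    missing <- setdiff(need, names(config$inputs))
    if (length(missing))
      v <- c(v, paste("missing input paths:", paste(missing, collapse = ", ")))
    for (nm in intersect(need, names(config$inputs)))
      if (!file.exists(config$inputs[[nm]]))
        v <- c(v, sprintf("input file '%s' not found: %s", nm,
                          config$inputs[[nm]]))
    if ("pheno" %in% names(config$inputs) &&
        file.exists(config$inputs$pheno)) {
      hdr <- strsplit(readLines(config$inputs$pheno, n = 1L), "\t")[[1]]
      if (!config$keyTrait %in% hdr)
        v <- c(v, sprintf("keyTrait '%s' is not a phenotype column",
                          config$keyTrait))
    }
  }
  if (config$alpha <= 0 || config$alpha > 1)
    v <- c(v, "alpha must lie in (0, 1]")
  if (config$minTraits < 1L) v <- c(v, "minTraits must be at least 1")
  if (config$window < 0L) v <- c(v, "window must be non-negative")
  if (config$mafMin < 0 || config$mafMin > 0.5)
    v <- c(v, "mafMin must lie in [0, 0.5]")
  if (config$missMax < 0 || config$missMax > 1)
    v <- c(v, "missMax must lie in [0, 1]")
  if (config$topK < 1L) v <- c(v, "topK must be at least 1")
  if (config$k < 1L) v <- c(v, "k must be at least 1")
  if (config$nIter < 1L) v <- c(v, "nIter must be at least 1")
  if (!config$perGeneRule %in% c("most_pleiotropic", "min_key_p"))
    v <- c(v, "perGeneRule must be 'most_pleiotropic' or 'min_key_p'")
  if (!config$countMode %in% c("targets", "edges"))
    v <- c(v, "countMode must be 'targets' or 'edges'")
  v
}

#' Run the full co-association analysis pipeline
#'
#' Simulate (or read) -> QC -> GRM -> per-trait REML + mixed-model GWAS ->
#' SNP selection -> gene annotation -> AWM -> trait relationships -> PCIT
#' -> network + topology -> regulator trios + key regulators (-> optional
#' random-subset heritability validation), writing every intermediate
#' artifact to `config$outDir` plus a manifest with per-stage counts and
#' file checksums. Reruns with the same config and seed are bit-identical.
#'
#' @param config a valid `awmRunConfig`.
#' @param quiet suppress the one-line-per-stage log.
#' @return the manifest, invisibly also written as `manifest.json`.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  viol <- validateConfig(config)
  if (length(viol))
    stop("invalid configuration:\n  - ", paste(viol, collapse = "\n  - "))
  t0 <- Sys.time()
  outDir <- config$outDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  else if (length(list.files(outDir)) && !config$force)
    stop("output directory '", outDir, "' is not empty; use force")
  note <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  written <- character()
  put <- function(name) written <<- c(written, file.path(outDir, name))

  # ---- inputs ----
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", simulateGenotypes(config$simulate))
    ts <- stage("simulate", simulateTraits(sim, config$simulate))
    geno0 <- sim$geno; genes <- sim$genes; census <- sim$census
    traitTable <- ts$traits
    note("simulate", "%d individuals, %d SNPs, %d traits, %d genes",
         nrow(dosages(geno0)), ncol(dosages(geno0)),
         ncol(traitValues(traitTable)), nrow(genes))
  } else {
    geno0 <- stage("read", readRawDosage(config$inputs$raw, config$inputs$map))
    traitTable <- stage("read", readPhenotypes(config$inputs$pheno))
    genes <- stage("read", readGeneAnnotation(config$inputs$annotation))
    census <- stage("read", readCensus(config$inputs$census))
    ord <- match(sampleIds(traitTable), sampleIds(geno0))
    if (anyNA(ord)) stop("stage 'read' failed: phenotype ids not in genotypes")
    geno0 <- methods::new("GenotypePanel",
                          dosage = dosages(geno0)[ord, , drop = FALSE],
                          snpInfo = snpInfo(geno0))
    note("read", "%d individuals, %d SNPs, %d traits",
         nrow(dosages(geno0)), ncol(dosages(geno0)),
         ncol(traitValues(traitTable)))
  }

  # ---- qc ----
  qc <- stage("qc", qcFilter(geno0, config$mafMin, config$missMax))
  geno <- qc$geno
  writeTsv(qc$report, file.path(outDir, "qc_report.tsv")); put("qc_report.tsv")
  note("qc", "retained %d / %d SNPs", ncol(dosages(geno)), ncol(dosages(geno0)))

  # ---- grm + gwas ----
  grm <- stage("grm", buildGRM(geno))
  gw <- stage("gwas", gwasAllTraits(geno, traitTable, grm))
  assoc <- gw$assoc
  h2Whole <- gw$h2
  writeTsv(h2Whole, file.path(outDir, "h2_whole_panel.tsv"))
  put("h2_whole_panel.tsv")
  note("gwas", "%d traits scanned; mean whole-panel h2 %.3f",
       nrow(h2Whole), mean(h2Whole$h2))

  # ---- selection + annotation ----
  sel <- stage("select", selectSnps(assoc, config$keyTrait, config$alpha,
                                    config$minTraits))
  note("select", "%d key-trait SNPs, %d pleiotropic, %d merged",
       length(sel$keyTraitSnps), length(sel$pleiotropicSnps),
       length(sel$merged))
  si <- snpInfo(geno)
  selSnps <- si[si$snp %in% sel$merged, c("snp", "chrom", "pos")]
  ann <- stage("annotate", annotateSnps(selSnps, genes, config$window))
  writeTsv(sel$perSnp[sel$perSnp$inKey | sel$perSnp$inPleio, ],
           file.path(outDir, "snp_selection.tsv")); put("snp_selection.tsv")
  writeTsv(ann$pairs, file.path(outDir, "snp_gene_pairs.tsv"))
  put("snp_gene_pairs.tsv")
  note("annotate", "%d pairs, %d genes, %d SNPs unannotated",
       nrow(ann$pairs), length(unique(ann$pairs$geneId)), ann$nUnannotated)
  if (!nrow(ann$pairs))
    stop("stage 'annotate' failed: no selected SNP maps to a gene")

  # ---- awm ----
  awm <- stage("awm", buildAWM(assoc, ann$pairs, config$keyTrait,
                               config$perGeneRule, config$alpha))
  z <- awmValues(awm)
  awmOut <- data.frame(geneId = rownames(z), snp = geneToSnp(awm), z,
                       check.names = FALSE)
  writeTsv(awmOut, file.path(outDir, "awm.tsv")); put("awm.tsv")
  rel <- stage("awm", traitRelationships(awm))
  writeLines(rel$newick, file.path(outDir, "trait_dendrogram.nwk"))
  put("trait_dendrogram.nwk")
  note("awm", "%d genes x %d traits", nrow(z), ncol(z))

  # ---- pcit + network ----
  gc <- stage("pcit", geneCorrelations(awm))
  mask <- stage("pcit", pcit(gc$r, maxN = config$pcitMaxN))
  net <- stage("network", buildNetwork(mask, gc$r, genes, census))
  topo <- stage("network", topologyStats(net))
  exportNetwork(net, file.path(outDir, "edges.tsv"),
                file.path(outDir, "network.graphml"))
  put("edges.tsv"); put("network.graphml")
  jsonlite::write_json(topo[setdiff(names(topo), "degree")],
                       file.path(outDir, "topology.json"),
                       auto_unbox = TRUE, digits = NA)
  put("topology.json")
  note("network", "%d nodes, %d edges, avg degree %.2f, clustering %.3f",
       topo$nNodes, topo$nEdges, topo$averageDegree,
       topo$clusteringCoefficient)

  # ---- regulators ----
  nodes <- networkNodes(net)
  trios <- NULL; keyRegs <- NULL
  if (sum(nodes$isRegulator) >= 3L) {
    tmap <- stage("regulators", targetSets(net))
    trios <- stage("regulators", rankTrios(tmap, config$topK,
                                           config$countMode))
    keyRegs <- stage("regulators",
                     selectKeyRegulators(tmap, min(config$k, length(tmap))))
    writeTsv(trios, file.path(outDir, "regulator_trios.tsv"))
    put("regulator_trios.tsv")
    jsonlite::write_json(keyRegs, file.path(outDir, "key_regulators.json"),
                         auto_unbox = TRUE, digits = NA)
    put("key_regulators.json")
    note("regulators", "%d regulators; best trio covers %d; %d key picks cover %d",
         length(tmap), trios$unionTargets[1], length(keyRegs$regulators),
         keyRegs$coverage)
  } else note("regulators", "fewer than 3 flagged regulators; stage skipped")

  # ---- optional subset-h2 validation ----
  h2Val <- NULL
  if (config$validateH2) {
    subsetIds <- unique(ann$pairs$snp)
    h2Val <- stage("validate-h2",
                   subsetH2Validation(geno, traitTable, subsetIds,
                                      nIter = config$nIter,
                                      seed = config$seed + 1000L))
    writeTsv(h2Val$perTrait, file.path(outDir, "h2_validation.tsv"))
    put("h2_validation.tsv")
    note("validate-h2", "focal subset beats all %d iterations for %d / %d traits",
         config$nIter, sum(h2Val$perTrait$rank == 1L), nrow(h2Val$perTrait))
  }

  # ---- manifest ----
  cfgEcho <- config
  cfgEcho$simulate <- if (!is.null(config$simulate))
    unclass(config$simulate) else NULL
  cfgEcho$outDir <- NULL              # run location, not analysis config
  cfgEcho$force <- NULL
  manifest <- list(
    package = as.character(utils::packageVersion("awmnet")),
    seed = config$seed,
    config = unclass(cfgEcho),
    counts = list(
      snpsInput = ncol(dosages(geno0)), snpsRetained = ncol(dosages(geno)),
      keyTraitSnps = length(sel$keyTraitSnps),
      pleiotropicSnps = length(sel$pleiotropicSnps),
      mergedSnps = length(sel$merged),
      mergedCheck = length(sel$keyTraitSnps) + length(sel$pleiotropicSnps) -
        length(intersect(sel$keyTraitSnps, sel$pleiotropicSnps)),
      annotatedSnps = length(unique(ann$pairs$snp)),
      genes = length(unique(ann$pairs$geneId)),
      nodes = topo$nNodes, edges = topo$nEdges,
      edgesCheck = sum(mask) / 2,
      regulators = sum(nodes$isRegulator)),
    topology = topo[setdiff(names(topo), "degree")],
    files = lapply(stats::setNames(nm = basename(written)), function(f)
      unname(tools::md5sum(file.path(outDir, f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  note("done", "wrote %d artifacts to %s in %.1fs", length(written) + 1L,
       outDir, as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(manifest)
}
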