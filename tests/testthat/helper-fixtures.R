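# shared fixture builders: everything is generated in code, tiny, and seeded

# AssocResults from p (and optional beta/se) matrices; rownames = SNP ids
makeAssoc <- function(p, beta = NULL, se = NULL, chrom = NULL, pos = NULL) {
  m <- nrow(p); nt <- ncol(p)
  if (is.null(beta)) beta <- matrix(1, m, nt, dimnames = dimnames(p))
  if (is.null(se)) se <- matrix(1, m, nt, dimnames = dimnames(p))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  si <- data.frame(snp = rownames(p), chrom = chrom, pos = pos,
                   alleleCounted = "B", alleleOther = "A",
                   maf = 0.3, callRate = 1, stringsAsFactors = FALSE)
  methods::new("AssocResults", beta = beta, se = se, p = p,
               nUsed = matrix(100L, m, nt, dimnames = dimnames(p)),
               untestable = matrix(FALSE, m, nt, dimnames = dimnames(p)),
               snpInfo = si)
}

# the printed toy fixture shipped under inst/extdata
toyFixture <- function() {
  dir <- system.file("extdata", package = "awmnet")
  assoc <- read.table(file.path(dir, "toy_assoc.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  traits <- sort(unique(assoc$trait))
  snps <- unique(assoc[, c("snp", "chrom", "pos")])
  shape <- function(col) {
    m <- matrix(NA_real_, nrow(snps), length(traits),
                dimnames = list(snps$snp, traits))
    m[cbind(match(assoc$snp, snps$snp), match(assoc$trait, traits))] <-
      assoc[[col]]
    m
  }
  list(assoc = makeAssoc(shape("p"), shape("beta"), shape("se"),
                         chrom = as.character(snps$chrom), pos = snps$pos),
       snps = transform(snps, chrom = as.character(chrom)),
       genes = readGeneAnnotation(file.path(dir, "toy_genes.gff3")),
       census = readCensus(file.path(dir, "toy_census.txt")),
       raw = assoc)
}

# small, fast simulation settings used across tests
tinySimConfig <- function(seed = 1L, ...) {
  args <- list(nIndividuals = 120L, nSnps = 600L, nChromosomes = 3L,
               nTraits = 6L,
               h2Targets = c(HCT = 0.4, LYM = 0.3, gdT = 0.45,
                             CRP = 0.2, PHAGO_PC = 0.3, NO = 0.25),
               nModules = 2L, genesPerModule = 4L, hubExtraTargets = 2L,
               nBackgroundGenes = 15L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simConfig, args)
}

# CoAssocNetwork straight from an edge list (for topology/regulator tests)
edgeNetwork <- function(nodes, edges, regulators = character()) {
  nd <- data.frame(gene = nodes, symbol = nodes,
                   isRegulator = nodes %in% regulators,
                   stringsAsFactors = FALSE)
  ed <- if (nrow(edges)) data.frame(from = pmin(edges[[1]], edges[[2]]),
                                    to = pmax(edges[[1]], edges[[2]]),
                                    weight = if (ncol(edges) > 2) edges[[3]] else 1,
                                    stringsAsFactors = FALSE)
        else data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  methods::new("CoAssocNetwork", nodes = nd, edges = ed)
}

# igraph twin of a CoAssocNetwork (independent topology oracle)
asIgraph <- function(net) {
  igraph::graph_from_data_frame(networkEdges(net), directed = FALSE,
                                vertices = networkNodes(net)$gene)
}

# random symmetric correlation matrix from a genes x traits data draw
randomCorr <- function(n, nt = 30L, seed = 1L) {
  set.seed(seed)
  R <- stats::cor(t(matrix(stats::rnorm(n * nt), n, nt)))
  dimnames(R) <- list(sprintf("g%02d", seq_len(n)), sprintf("g%02d", seq_len(n)))
  R
}
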