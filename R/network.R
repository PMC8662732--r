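#' Build the gene co-association network
#'
#' Nodes are all genes (isolated nodes retained and counted); edges are
#' the PCIT-significant pairs, weighted by the direct correlation of the
#' two genes' effect profiles. Regulator nodes are flagged by
#' case-insensitive symbol match against the census.
#'
#' @param mask logical significance matrix from [pcit()] (symmetric,
#'   `FALSE` diagonal), dimnames = gene ids.
#' @param corr the correlation matrix the mask came from.
#' @param genes gene annotation `data.frame` (`geneId`, `symbol`); rows
#'   not in the mask are ignored.
#' @param census character vector of regulator symbols; an empty census
#'   gives all-FALSE flags with a warning.
#' @return a [CoAssocNetwork-class].
#' @export
buildNetwork <- function(mask, corr, genes, census = character()) {
  ids <- rownames(mask)
  if (is.null(ids)) stop("mask needs gene ids as dimnames")
  if (!isTRUE(all.equal(mask, t(mask)))) stop("mask must be symmetric")
  if (any(diag(mask))) stop("mask must have a FALSE diagonal (no self-edges)")
  sym <- genes$symbol[match(ids, genes$geneId)]
  sym[is.na(sym)] <- ids[is.na(sym)]
  if (!length(census)) {
    warning("empty regulator census: no regulator flags set")
    isReg <- rep(FALSE, length(ids))
  } else isReg <- toupper(sym) %in% toupper(census)
  nodes <- data.frame(gene = ids, symbol = sym, isRegulator = isReg,
                      stringsAsFactors = FALSE)
  ut <- which(upper.tri(mask) & mask, arr.ind = TRUE)
  edges <- data.frame(from = ids[ut[, 1]], to = ids[ut[, 2]],
                      weight = corr[ut], stringsAsFactors = FALSE)
  methods::new("CoAssocNetwork", nodes = nodes, edges = edges)
}

# adjacency list (integer neighbour indices per node)
adjacencyList <- function(network) {
  ids <- networkNodes(network)$gene
  e <- networkEdges(network)
  i <- match(e$from, ids); j <- match(e$to, ids)
  adj <- vector("list", length(ids))
  for (k in seq_along(ids)) adj[[k]] <- integer()
  if (nrow(e)) {
    spl <- split(c(j, i), c(i, j))
    for (nm in names(spl)) adj[[as.integer(nm)]] <- sort(unique(spl[[nm]]))
  }
  names(adj) <- ids
  adj
}

#' Network topology statistics
#'
#' Degree, mean local clustering coefficient, average shortest-path length
#' and connected components, computed by the package's own BFS:
#' \itemize{
#'   \item clustering: per node, closed-triple fraction among its
#'     neighbours; nodes with degree < 2 contribute 0 by default
#'     (`degreeLT2 = "zero"`, the common network-analyzer convention) or
#'     are excluded (`degreeLT2 = "exclude"`).
#'   \item path length: mean BFS distance over connected distinct pairs
#'     within components (disconnected pairs reported, never averaged as
#'     infinity).
#' }
#'
#' @param network a [CoAssocNetwork-class].
#' @param degreeLT2 handling of degree-0/1 nodes in the mean clustering.
#' @return list: `nNodes`, `nEdges`, `averageDegree`,
#'   `clusteringCoefficient`, `averagePathLength` (`NA` if no connected
#'   pair), `nComponents`, `nIsolated`, `nDisconnectedPairs`, `degree`
#'   (named vector).
#' @export
topologyStats <- function(network, degreeLT2 = c("zero", "exclude")) {
  degreeLT2 <- match.arg(degreeLT2)
  adj <- adjacencyList(network)
  n <- length(adj)
  deg <- lengths(adj)
  nE <- nrow(networkEdges(network))

  localC <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]; d <- length(nb)
    if (d < 2L) { localC[v] <- 0; next }
    links <- 0L
    nbSet <- nb
    for (u in nb) links <- links + sum(adj[[u]] %in% nbSet)
    localC[v] <- links / (d * (d - 1L))   # each link counted twice
  }
  cc <- if (degreeLT2 == "zero") mean(localC)
        else if (any(deg >= 2L)) mean(localC[deg >= 2L]) else 0

  # BFS from every node: component labels + pairwise distances
  comp <- integer(n); nc <- 0L
  totDist <- 0; nPairs <- 0
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {               # label a new component
      nc <- nc + 1L
      queue <- s; comp[s] <- nc
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        for (u in adj[[v]]) if (comp[u] == 0L) { comp[u] <- nc; queue <- c(queue, u) }
      }
    }
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in adj[[v]]) if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L; queue <- c(queue, u)
      }
    }
    reach <- which(!is.na(dist) & seq_len(n) != s)
    totDist <- totDist + sum(dist[reach])
    nPairs <- nPairs + length(reach)
  }
  csize <- tabulate(comp, nc)
  list(nNodes = n, nEdges = nE,
       averageDegree = if (n) 2 * nE / n else 0,
       clusteringCoefficient = cc,
       averagePathLength = if (nPairs) totDist / nPairs else NA_real_,
       nComponents = nc, nIsolated = sum(deg == 0L),
       nDisconnectedPairs = (n * (n - 1L) - nPairs) / 2,
       degree = stats::setNames(deg, names(adj)))
}

#' Export a network for Cytoscape
#'
#' Writes the edge list as TSV and the full network as GraphML (via
#' igraph), with `isRegulator` and `symbol` node attributes.
#'
#' @param network a [CoAssocNetwork-class].
#' @param edgeTsv,graphml output paths (`NULL` to skip either).
#' @return invisibly, the paths written.
#' @export
exportNetwork <- function(network, edgeTsv = NULL, graphml = NULL) {
  out <- character()
  if (!is.null(edgeTsv)) {
    writeTsv(networkEdges(network), edgeTsv)
    out <- c(out, edgeTsv)
  }
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      networkEdges(network), directed = FALSE,
      vertices = networkNodes(network))
    igraph::write_graph(g, graphml, format = "graphml")
    out <- c(out, graphml)
  }
  invisible(out)
}
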