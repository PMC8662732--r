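#' Target sets of flagged regulators
#'
#' For each regulator node, its set of network neighbours (other
#' regulators count as targets; the regulator itself never does).
#' Isolated regulators are retained with an empty set.
#'
#' @param network a [CoAssocNetwork-class] with at least one flagged
#'   regulator.
#' @return named list of character vectors (sorted gene ids), one per
#'   regulator.
#' @export
targetSets <- function(network) {
  nodes <- networkNodes(network)
  regs <- nodes$gene[nodes$isRegulator]
  if (!length(regs)) stop("network has no flagged regulators")
  adj <- adjacencyList(network)
  ids <- nodes$gene
  out <- lapply(regs, function(r) sort(ids[adj[[match(r, ids)]]]))
  names(out) <- regs
  out
}

# trio score: unique non-member coverage; redundancy: non-member genes
# covered by >= 2 members
trioScore <- function(targetMap, members, countMode = "targets") {
  if (countMode == "targets") {
    tgt <- lapply(targetMap[members], function(s) setdiff(unique(s), members))
    un <- unique(unlist(tgt, use.names = FALSE))
    mult <- table(unlist(tgt, use.names = FALSE))
    c(score = length(un), redundancy = sum(mult >= 2L))
  } else {                            # "edges": union of incident edges
    edges <- unlist(lapply(members, function(m)
      paste(pmin(m, targetMap[[m]]), pmax(m, targetMap[[m]]))),
      use.names = FALSE)
    c(score = length(unique(edges)), redundancy = sum(table(edges) >= 2L))
  }
}

#' Rank regulator trios by unique network coverage
#'
#' Exhaustively enumerates all C(R, 3) regulator trios and scores each by
#' the number of unique genes connected to at least one member, excluding
#' the members themselves (`countMode = "targets"`, the default reading of
#' "unique interactions"; `countMode = "edges"` counts the union of
#' incident edges instead). Ordering: score descending, ties by lower
#' redundancy (genes reached by two or more members), ties by the
#' lexicographic sorted member triple.
#'
#' @param targetMap named list from [targetSets()] (or any regulator ->
#'   target-id-vector map); needs >= 3 regulators.
#' @param topK how many trios to return (default 10).
#' @param countMode `"targets"` or `"edges"` (see above).
#' @return `data.frame`: `member1..3` (sorted within trio), `unionTargets`,
#'   `redundancy`, best trio first.
#' @export
rankTrios <- function(targetMap, topK = 10L, countMode = c("targets", "edges")) {
  countMode <- match.arg(countMode)
  regs <- sort(names(targetMap))
  if (length(regs) < 3L) stop("need at least 3 regulators")
  combos <- utils::combn(regs, 3L)
  sc <- apply(combos, 2L, function(m) trioScore(targetMap, m, countMode))
  res <- data.frame(member1 = combos[1, ], member2 = combos[2, ],
                    member3 = combos[3, ],
                    unionTargets = sc["score", ],
                    redundancy = sc["redundancy", ],
                    stringsAsFactors = FALSE)
  o <- order(-res$unionTargets, res$redundancy,
             res$member1, res$member2, res$member3)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, topK)
}

#' Greedy maximum-coverage key-regulator selection
#'
#' Repeatedly picks the regulator adding the most not-yet-covered target
#' genes (maximum coverage with minimum overlap); ties go to the larger
#' total target set, then the lexicographically smaller id. Stops early
#' when no pick adds a positive gain, so every retained pick has a
#' strictly positive marginal gain. An exhaustive mode searches all
#' C(R, k) subsets for the true optimum on small inputs.
#'
#' @param targetMap named list of regulator target sets.
#' @param k maximum number of regulators to select (>= 1).
#' @param exhaustive search all subsets of size <= k (only allowed for
#'   <= 25 regulators).
#' @return list: `regulators` (ordered picks), `coveredGenes` (sorted
#'   union), `marginalGains` (named, per pick), `coverage` (count).
#' @export
selectKeyRegulators <- function(targetMap, k = 5L, exhaustive = FALSE) {
  if (k < 1L) stop("k must be at least 1")
  if (k > length(targetMap)) stop("k exceeds the number of regulators")
  targetMap <- lapply(targetMap, unique)
  if (exhaustive) {
    if (length(targetMap) > 25L)
      stop("exhaustive search limited to 25 regulators")
    regs <- sort(names(targetMap))
    best <- NULL; bestCov <- -1L
    for (kk in seq_len(k)) {
      combos <- utils::combn(regs, kk)
      for (j in seq_len(ncol(combos))) {
        cov <- length(unique(unlist(targetMap[combos[, j]], use.names = FALSE)))
        if (cov > bestCov) { bestCov <- cov; best <- combos[, j] }
      }
    }
    covered <- sort(unique(unlist(targetMap[best], use.names = FALSE)))
    return(list(regulators = best, coveredGenes = covered,
                marginalGains = NULL, coverage = length(covered)))
  }
  totSize <- lengths(targetMap)
  covered <- character()
  picks <- character(); gains <- integer()
  remaining <- sort(names(targetMap))
  for (step in seq_len(k)) {
    gain <- vapply(remaining,
                   function(r) length(setdiff(targetMap[[r]], covered)),
                   integer(1))
    if (!length(gain) || max(gain) <= 0L) break
    cand <- remaining[gain == max(gain)]
    if (length(cand) > 1L) {
      cand <- cand[totSize[cand] == max(totSize[cand])]
      cand <- sort(cand)[1L]
    }
    picks <- c(picks, cand)
    gains <- c(gains, max(gain))
    covered <- union(covered, targetMap[[cand]])
    remaining <- setdiff(remaining, cand)
  }
  list(regulators = picks, coveredGenes = sort(covered),
       marginalGains = stats::setNames(gains, picks),
       coverage = length(covered))
}
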