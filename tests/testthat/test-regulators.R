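test_that("target sets are network neighbourhoods, self excluded", {
  star <- edgeNetwork(c("R1", "l1", "l2", "l3", "l4", "R2"),
                      data.frame(f = c("R1", "R1", "R1", "R1"),
                                 t = c("l1", "l2", "l3", "l4")),
                      regulators = c("R1", "R2"))
  tm <- targetSets(star)
  expect_identical(tm$R1, c("l1", "l2", "l3", "l4"))
  expect_identical(tm$R2, character(0))      # isolated regulator retained
  expect_error(targetSets(edgeNetwork("a", data.frame(f = character(),
                                                      t = character()))),
               "no flagged regulators")

  # random graph: sets equal an adjacency-row recomputation
  set.seed(139)
  nodes <- sprintf("n%02d", 1:20)
  pairs <- t(combn(nodes, 2))
  sel <- runif(nrow(pairs)) < 0.2
  net <- edgeNetwork(nodes, as.data.frame(pairs[sel, , drop = FALSE]),
                     regulators = nodes[1:5])
  tm2 <- targetSets(net)
  e <- networkEdges(net)
  for (r in names(tm2)) {
    nb <- sort(unique(c(e$to[e$from == r], e$from[e$to == r])))
    expect_identical(tm2[[r]], nb)
  }
})

test_that("trio ranking scores unique coverage with redundancy tie-break", {
  tm <- list(A = c("1", "2", "3"), B = c("3", "4"), C = "5", D = c("1", "5"))
  rk <- rankTrios(tm, topK = 4)
  # best score 5 by {A,B,C} and {A,B,D}; {A,B,C} first on lower redundancy
  expect_identical(unlist(rk[1, 1:3], use.names = FALSE), c("A", "B", "C"))
  expect_identical(rk$unionTargets[1], 5L)
  expect_identical(rk$redundancy[1], 1L)
  expect_identical(unlist(rk[2, 1:3], use.names = FALSE), c("A", "B", "D"))
  expect_identical(rk$redundancy[2], 2L)

  # all sets identical: pure lexicographic ordering
  same <- list(Z = c("1", "2"), Y = c("1", "2"), X = c("1", "2"),
               W = c("1", "2"))
  rs <- rankTrios(same, topK = 4)
  expect_identical(unlist(rs[1, 1:3], use.names = FALSE), c("W", "X", "Y"))
  expect_true(all(rs$unionTargets == 2L))
  expect_error(rankTrios(tm[1:2]), "at least 3")
})

test_that("trio ranking equals a naive enumerator and ignores input order", {
  set.seed(149)
  for (rep in 1:5) {
    tm <- lapply(setNames(nm = sprintf("R%02d", 1:15)), function(.)
      sample(sprintf("g%02d", 1:40), sample(0:12, 1)))
    rk <- rankTrios(tm, topK = Inf)
    # independent enumerator: data.frame of all triples, base sorting
    regs <- names(tm)
    cmb <- combn(regs, 3)
    naive <- data.frame(t(cmb), stringsAsFactors = FALSE)
    naive$score <- naive$red <- 0L
    for (i in seq_len(ncol(cmb))) {
      mem <- cmb[, i]
      covered <- setdiff(unlist(tm[mem]), mem)
      naive$score[i] <- length(unique(covered))
      cnt <- table(unlist(lapply(tm[mem], function(s) unique(setdiff(s, mem)))))
      naive$red[i] <- sum(cnt >= 2)
    }
    naive <- naive[order(-naive$score, naive$red, naive$X1, naive$X2,
                         naive$X3), ]
    expect_identical(rk$member1, naive$X1)
    expect_identical(rk$member2, naive$X2)
    expect_identical(rk$member3, naive$X3)
    expect_identical(rk$unionTargets, naive$score)
    # permutation invariance in regulator input order
    rk2 <- rankTrios(tm[sample(length(tm))], topK = Inf)
    expect_identical(rk, rk2)
  }
})

test_that("greedy key-regulator selection follows the documented rules", {
  tm <- list(A = as.character(1:10), B = as.character(c(1:9, 11)),
             C = c("20", "21"))
  ks <- selectKeyRegulators(tm, k = 2)
  expect_identical(ks$regulators, c("A", "C"))   # B adds only 1 new gene
  expect_identical(unname(ks$marginalGains), c(10L, 2L))
  expect_identical(ks$coverage, 12L)

  # disjoint sets: greedy = sort by size, coverage = sum of sizes
  dj <- list(P = as.character(1:5), Q = as.character(6:8),
             R = as.character(9:15))
  kd <- selectKeyRegulators(dj, k = 3)
  expect_identical(kd$regulators, c("R", "P", "Q"))
  expect_identical(kd$coverage, 15L)

  # early stop: picks with zero gain are dropped
  ov <- list(M = c("1", "2"), N = c("1", "2"), O = character(0))
  ko <- selectKeyRegulators(ov, k = 3)
  expect_identical(ko$regulators, "M")
  expect_true(all(ko$marginalGains > 0))
  expect_error(selectKeyRegulators(tm, k = 0), "at least 1")
  expect_error(selectKeyRegulators(tm, k = 9), "exceeds")
})

test_that("greedy coverage dominates the best trio and nears the optimum", {
  set.seed(151)
  for (rep in 1:5) {
    tm <- lapply(setNames(nm = sprintf("R%02d", 1:12)), function(.)
      sample(sprintf("g%02d", 1:30), sample(1:10, 1)))
    greedy3 <- selectKeyRegulators(tm, k = 3)$coverage
    bestTrio <- rankTrios(tm, topK = 1)$unionTargets[1]
    expect_gte(greedy3, bestTrio)
    # (1 - 1/e) bound against the exhaustive optimum at k = 4
    opt <- selectKeyRegulators(tm, k = 4, exhaustive = TRUE)$coverage
    expect_gte(selectKeyRegulators(tm, k = 4)$coverage, (1 - exp(-1)) * opt)
  }
})

test_that("planted hub regulators dominate the greedy picks", {
  ok <- 0L
  for (s in 1:10) {
    mp <- simulateModuleProfiles(nTraits = 30, nModules = 3,
                                 genesPerModule = 20, hubExtraTargets = 15,
                                 moduleCor = 0.8, nBackground = 40,
                                 seed = 400 + s)
    R <- cor(t(mp$profiles))
    sig <- pcit(R)
    genes <- data.frame(geneId = rownames(R), symbol = rownames(R),
                        stringsAsFactors = FALSE)
    set.seed(s)
    census <- c(mp$hubs, sample(rownames(R)[mp$membership == 0], 10))
    net <- buildNetwork(sig, R, genes, census)
    picks <- selectKeyRegulators(targetSets(net), k = 6)$regulators
    ok <- ok + all(mp$hubs %in% picks)
  }
  expect_gte(ok, 9L)
})
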