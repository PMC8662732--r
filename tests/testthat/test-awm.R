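test_that("SNP selection applies strict nominal thresholds and merges", {
  traits <- c("key", "t2", "t3", "t4")
  p <- matrix(1, 5, 4, dimnames = list(paste0("SNP", 1:5), traits))
  p["SNP1", "key"] <- 0.01                      # key-only
  p["SNP2", c("t2", "t3", "t4")] <- 0.02        # pleiotropic (3 traits)
  p["SNP3", c("key", "t2", "t3")] <- 0.03       # both lists
  p["SNP4", "key"] <- 0.05                      # boundary: excluded
  assoc <- makeAssoc(p)
  sel <- selectSnps(assoc, "key", alpha = 0.05, minTraits = 3)
  expect_identical(sel$keyTraitSnps, c("SNP1", "SNP3"))
  expect_identical(sel$pleiotropicSnps, c("SNP2", "SNP3"))
  expect_identical(sel$merged, c("SNP1", "SNP2", "SNP3"))
  # independent recount, element by element
  for (s in rownames(p)) {
    nHit <- sum(p[s, ] < 0.05)
    expect_identical(s %in% sel$merged, p[s, "key"] < 0.05 || nHit >= 3)
    expect_identical(unname(sel$perSnp$nAssocTraits[sel$perSnp$snp == s]),
                     as.integer(nHit))
  }
  expect_error(selectSnps(assoc, "nope"), "unknown key trait")

  pAll1 <- matrix(1, 3, 4, dimnames = list(paste0("x", 1:3), traits))
  sel0 <- selectSnps(makeAssoc(pAll1), "key")
  expect_length(sel0$merged, 0)
})

test_that("merged-set union arithmetic holds on random p matrices", {
  set.seed(101)
  for (rep in 1:10) {
    p <- matrix(runif(60 * 8), 60, 8,
                dimnames = list(sprintf("r%02d", 1:60), paste0("t", 1:8)))
    sel <- selectSnps(makeAssoc(p), "t1", alpha = 0.2, minTraits = 3)
    expect_identical(length(sel$merged),
                     length(sel$keyTraitSnps) + length(sel$pleiotropicSnps) -
                       length(intersect(sel$keyTraitSnps, sel$pleiotropicSnps)))
  }
})

test_that("annotation windows are inclusive, chrom-aware and monotone", {
  genes <- data.frame(geneId = "G1", symbol = "G1", chrom = "1",
                      start = 20000L, end = 30000L, strand = "+",
                      stringsAsFactors = FALSE)
  snps <- data.frame(snp = c("a", "b", "c", "d"),
                     chrom = c("1", "1", "2", "1"),
                     pos = c(15000L, 14999L, 15000L, 35000L),
                     stringsAsFactors = FALSE)
  ann <- annotateSnps(snps, genes, window = 5000)
  expect_identical(sort(ann$pairs$snp), c("a", "d"))  # start-5000 in, end+5000 in
  expect_false("b" %in% ann$pairs$snp)                # start-5001 out
  expect_false("c" %in% ann$pairs$snp)                # wrong chromosome
  expect_identical(ann$nUnannotated, 2L)
  expect_error(annotateSnps(snps, genes, window = -1), "non-negative")

  # random fixture vs an all-pairs interval oracle; monotone in window
  set.seed(103)
  genes2 <- data.frame(geneId = sprintf("G%02d", 1:80),
                       symbol = sprintf("G%02d", 1:80),
                       chrom = sample(c("1", "2", "3"), 80, TRUE),
                       start = st <- sample.int(9e5, 80),
                       end = st + sample.int(5e4, 80),
                       strand = "+", stringsAsFactors = FALSE)
  snps2 <- data.frame(snp = sprintf("s%03d", 1:500),
                      chrom = sample(c("1", "2", "3"), 500, TRUE),
                      pos = sample.int(1e6, 500), stringsAsFactors = FALSE)
  key <- function(pr) sort(paste(pr$snp, pr$geneId))
  prev <- character()
  for (w in c(0, 5000, 20000)) {
    got <- annotateSnps(snps2, genes2, window = w)$pairs
    oracle <- character()
    for (i in seq_len(nrow(snps2))) for (j in seq_len(nrow(genes2)))
      if (snps2$chrom[i] == genes2$chrom[j] &&
          snps2$pos[i] >= genes2$start[j] - w &&
          snps2$pos[i] <= genes2$end[j] + w)
        oracle <- c(oracle, paste(snps2$snp[i], genes2$geneId[j]))
    expect_identical(key(got), sort(oracle))
    expect_true(all(prev %in% key(got)))      # pairs(w1) subset of pairs(w2)
    prev <- key(got)
  }
})

test_that("the AWM standardizes per-gene representative t-values by column", {
  toy <- toyFixture()
  sel <- selectSnps(toy$assoc, "T1")
  ann <- annotateSnps(toy$snps[toy$snps$snp %in% sel$merged, ], toy$genes)
  awm <- buildAWM(toy$assoc, ann$pairs, "T1")
  z <- awmValues(awm)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, var) - 1)), 1e-8)
  # representative SNP: GENE_C sees S04 (4 assoc traits) and S05 (2) -> S04
  expect_identical(unname(geneToSnp(awm)["GENE_C"]), "S04")
  # genes sharing a SNP get the same row of t-values
  g <- geneToSnp(awm)
  tv <- assocBeta(toy$assoc) / assocSE(toy$assoc)
  raw <- tv[g, , drop = FALSE]
  expect_equal(unname(scale(raw)[, 1]), unname(z[, 1]))

  # exact closed form: standardized {1,2,3} -> {-1,0,1} with sample SD
  p1 <- matrix(c(0.01, 0.01, 0.01), 3, 1,
               dimnames = list(c("a", "b", "c"), "T1"))
  assoc1 <- makeAssoc(cbind(T1 = c(.01, .01, .01),
                            T2 = c(.5, .5, .5), T3 = c(.9, .9, .9)) |>
                        `rownames<-`(c("a", "b", "c")),
                      beta = cbind(T1 = 1:3, T2 = c(1, 3, 2), T3 = c(2, 1, 3)) |>
                        `rownames<-`(c("a", "b", "c")))
  prs <- data.frame(snp = c("a", "b", "c"), geneId = c("g1", "g2", "g3"))
  z1 <- awmValues(buildAWM(assoc1, prs, "T1"))
  expect_equal(unname(z1[, "T1"]), c(-1, 0, 1))
})

test_that("AWM construction is invariant to gene input order", {
  toy <- toyFixture()
  sel <- selectSnps(toy$assoc, "T1")
  ann <- annotateSnps(toy$snps[toy$snps$snp %in% sel$merged, ], toy$genes)
  a1 <- buildAWM(toy$assoc, ann$pairs, "T1")
  shuffled <- ann$pairs[rev(seq_len(nrow(ann$pairs))), ]
  a2 <- buildAWM(toy$assoc, shuffled, "T1")
  expect_identical(awmValues(a1), awmValues(a2))
  expect_identical(geneToSnp(a1), geneToSnp(a2))
})

test_that("a constant trait column is an error naming the trait", {
  p <- matrix(0.01, 3, 3, dimnames = list(c("a", "b", "c"), c("T1", "T2", "T3")))
  beta <- p; beta[] <- c(1, 2, 3, 5, 5, 5, 1, 3, 2)   # T2 constant t-values
  assoc <- makeAssoc(p, beta = beta)
  prs <- data.frame(snp = c("a", "b", "c"), geneId = c("g1", "g2", "g3"))
  expect_error(buildAWM(assoc, prs, "T1"), "T2")
})

test_that("trait relationships recover planted correlation structure", {
  # two identical columns: r = 1, merged first at height 0; a column and its
  # negation: r = -1, distance 2
  set.seed(107)
  base <- rnorm(40)
  z <- cbind(A = base, B = base, C = -base, D = rnorm(40))
  z <- scale(z); attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  rownames(z) <- sprintf("g%02d", 1:40)
  awm <- methods::new("AWMatrix", z = z,
                      geneToSnp = setNames(sprintf("s%02d", 1:40), rownames(z)),
                      keyTrait = "A")
  rel <- traitRelationships(awm)
  expect_equal(rel$correlation["A", "B"], 1)
  expect_equal(rel$correlation["A", "C"], -1)
  expect_equal(rel$hclust$height[1], 0, tolerance = 1e-12)
  first <- rel$hclust$merge[1, ]
  expect_setequal(rel$hclust$labels[-first], c("A", "B"))

  # two planted trait blocks are recovered by a 2-cluster cut
  hits <- vapply(1:20, function(s) {
    set.seed(200 + s)
    g <- 60
    lat <- matrix(rnorm(2 * g), g, 2)
    cols <- cbind(lat[, 1] + 0.4 * matrix(rnorm(g * 4), g, 4),
                  lat[, 2] + 0.4 * matrix(rnorm(g * 4), g, 4))
    colnames(cols) <- paste0("t", 1:8)
    rownames(cols) <- sprintf("g%02d", 1:g)
    zz <- scale(cols); attr(zz, "scaled:center") <- attr(zz, "scaled:scale") <- NULL
    aw <- methods::new("AWMatrix", z = zz,
                       geneToSnp = setNames(sprintf("s%02d", 1:g), rownames(zz)),
                       keyTrait = "t1")
    cl <- traitRelationships(aw, k = 2)$clusters
    length(unique(cl[1:4])) == 1 && length(unique(cl[5:8])) == 1 &&
      cl[1] != cl[5]
  }, logical(1))
  expect_gte(sum(hits), 18)
})
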