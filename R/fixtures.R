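#' Write a complete study fixture to disk
#'
#' Serialises a simulated study as the plain-text formats the pipeline
#' readers consume: PLINK `.ped`/`.map` (alleles A/B, missing `0 0`),
#' PLINK additive `.raw` dosage, a phenotype/covariate TSV, GFF3 gene
#' annotation, a regulator census (one symbol per line) and a ground-truth
#' JSON. All files round-trip losslessly through the package readers.
#'
#' @param dir output directory (created if needed).
#' @param sim result of [simulateGenotypes()].
#' @param traitsSim result of [simulateTraits()] (optional; omit to write
#'   genotypes/annotation only).
#' @param force overwrite an existing fixture.
#' @return invisibly, a named character vector of the files written.
#' @export
writeFixture <- function(dir, sim, traitsSim = NULL, force = FALSE) {
  files <- c(ped = "geno.ped", map = "geno.map", raw = "geno.raw",
             pheno = "phenotypes.tsv", gff3 = "genes.gff3",
             census = "census.txt", truth = "truth.json")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  else if (any(file.exists(paths)) && !force)
    stop("fixture files already exist in '", dir, "'; use force = TRUE")

  geno <- sim$geno
  d <- dosages(geno)
  si <- snpInfo(geno)
  n <- nrow(d); m <- ncol(d)
  sex <- if (!is.null(traitsSim))
    ifelse(covariates(traitsSim$traits)$sex == "M", 1L, 2L) else rep(0L, n)

  # .map: chrom, id, genetic distance 0, position
  utils::write.table(
    data.frame(si$chrom, si$snp, 0L, si$pos),
    paths["map"], sep = " ", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  # .ped: FID IID PAT MAT SEX PHENO + two alleles per SNP
  alleleStr <- matrix("0 0", n, m)
  a <- si$alleleOther; b <- si$alleleCounted
  for (v in 0:2) {
    idx <- which(!is.na(d) & d == v, arr.ind = TRUE)
    if (!nrow(idx)) next
    j <- idx[, 2]
    alleleStr[idx] <- switch(as.character(v),
      "0" = paste(a[j], a[j]), "1" = paste(a[j], b[j]),
      "2" = paste(b[j], b[j]))
  }
  pedLines <- paste(rownames(d), rownames(d), 0L, 0L, sex, -9L,
                    apply(alleleStr, 1L, paste, collapse = " "))
  writeLines(pedLines, paths["ped"])

  # .raw: additive dosage of the counted allele
  rawHdr <- paste(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
                    paste0(si$snp, "_", si$alleleCounted)), collapse = " ")
  body <- cbind(rownames(d), rownames(d), 0L, 0L, sex, -9L,
                ifelse(is.na(d), "NA", as.character(d)))
  writeLines(c(rawHdr, apply(body, 1L, paste, collapse = " ")), paths["raw"])

  # GFF3 gene annotation (1-based closed)
  g <- sim$genes
  attrs <- sprintf("ID=%s;Name=%s;module=%d;hub=%s",
                   g$geneId, g$symbol, g$module, tolower(g$isHub))
  gff <- paste(g$chrom, "awmnet", "gene", g$start, g$end, ".",
               g$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", gff), paths["gff3"])

  writeLines(sim$census, paths["census"])

  if (!is.null(traitsSim)) {
    tt <- traitsSim$traits
    ph <- data.frame(id = rownames(traitValues(tt)),
                     covariates(tt), traitValues(tt),
                     check.names = FALSE, stringsAsFactors = FALSE)
    writeTsv(ph, paths["pheno"])
    tr <- traitsSim$truth
    jsonlite::write_json(
      list(causalMap = tr$causalMap,
           hubGenes = tr$hubGenes,
           trueH2 = as.list(tr$trueH2),
           effects = list(genes = rownames(tr$effects),
                          traits = colnames(tr$effects),
                          values = unname(tr$effects))),
      paths["truth"], digits = NA, auto_unbox = TRUE)
  } else paths <- paths[!names(paths) %in% c("pheno", "truth")]
  invisible(paths)
}

#' Read PLINK additive dosage (.raw) with its .map
#'
#' @param rawPath path to a PLINK `.raw` file (header `FID IID PAT MAT SEX
#'   PHENOTYPE` then one `SNP_allele` column per SNP).
#' @param mapPath path to the matching `.map` (chrom, id, cM, position).
#' @return a [GenotypePanel-class]; MAF and call rate recomputed from the
#'   dosages.
#' @export
readRawDosage <- function(rawPath, mapPath) {
  hdr <- strsplit(readLines(rawPath, n = 1L), "[ \t]+")[[1]]
  snpCols <- hdr[-(1:6)]
  snp <- sub("_[^_]+$", "", snpCols)
  counted <- sub("^.*_", "", snpCols)
  raw <- utils::read.table(rawPath, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  d <- as.matrix(raw[, -(1:6), drop = FALSE])
  storage.mode(d) <- "double"
  dimnames(d) <- list(raw$IID, snp)
  map <- utils::read.table(mapPath, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp", "cm", "pos"))
  ord <- match(snp, map$snp)
  if (anyNA(ord)) stop(".map does not cover all .raw SNP columns")
  p <- colMeans(d, na.rm = TRUE) / 2
  si <- data.frame(snp = snp, chrom = as.character(map$chrom[ord]),
                   pos = map$pos[ord], alleleCounted = counted,
                   alleleOther = ifelse(counted == "B", "A", "B"),
                   maf = pmin(p, 1 - p), callRate = colMeans(!is.na(d)),
                   stringsAsFactors = FALSE)
  methods::new("GenotypePanel", dosage = d, snpInfo = si)
}

#' Read PLINK .ped/.map genotypes
#'
#' Counts `countedAllele` copies to form the additive dosage; `0 0` is
#' treated as missing.
#'
#' @param pedPath,mapPath PLINK text file paths.
#' @param countedAllele allele whose copies are counted (default `"B"`).
#' @return a [GenotypePanel-class].
#' @export
readPedMap <- function(pedPath, mapPath, countedAllele = "B") {
  map <- utils::read.table(mapPath, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp", "cm", "pos"))
  m <- nrow(map)
  lines <- readLines(pedPath)
  toks <- strsplit(lines, "[ \t]+")
  n <- length(toks)
  d <- matrix(NA_real_, n, m)
  ids <- character(n)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) != 6L + 2L * m)
      stop(sprintf(".ped line %d has %d fields, expected %d",
                   i, length(tk), 6L + 2L * m))
    ids[i] <- tk[2]
    a1 <- tk[seq(7L, by = 2L, length.out = m)]
    a2 <- tk[seq(8L, by = 2L, length.out = m)]
    ok <- a1 != "0" & a2 != "0"
    d[i, ok] <- (a1[ok] == countedAllele) + (a2[ok] == countedAllele)
  }
  dimnames(d) <- list(ids, map$snp)
  p <- colMeans(d, na.rm = TRUE) / 2
  si <- data.frame(snp = map$snp, chrom = as.character(map$chrom),
                   pos = map$pos, alleleCounted = countedAllele,
                   alleleOther = ifelse(countedAllele == "B", "A", "B"),
                   maf = pmin(p, 1 - p), callRate = colMeans(!is.na(d)),
                   stringsAsFactors = FALSE)
  methods::new("GenotypePanel", dosage = d, snpInfo = si)
}

#' Read a phenotype/covariate TSV
#'
#' Expects columns `id`, `sex`, `batch`, `labBatch` then one numeric column
#' per trait (`NA` for missing). The per-trait analysis spec defaults to
#' the lab-batch factor for traits whose name contains `PHAGO` and no log
#' transform; pass `spec` to override.
#'
#' @param path TSV path.
#' @param spec optional `data.frame(trait, batchFactor, logTransform)`.
#' @return a [TraitTable-class].
#' @export
readPhenotypes <- function(path, spec = NULL) {
  ph <- readTsv(path)
  need <- c("id", "sex", "batch", "labBatch")
  if (!all(need %in% names(ph)))
    stop("phenotype table must have columns id, sex, batch, labBatch")
  traitCols <- setdiff(names(ph), need)
  Y <- as.matrix(ph[, traitCols, drop = FALSE])
  storage.mode(Y) <- "double"
  rownames(Y) <- ph$id
  cov <- data.frame(sex = factor(ph$sex), batch = factor(ph$batch),
                    labBatch = factor(ph$labBatch), row.names = ph$id)
  if (is.null(spec))
    spec <- data.frame(trait = traitCols,
                       batchFactor = ifelse(grepl("PHAGO", traitCols),
                                            "labBatch", "batch"),
                       logTransform = FALSE, stringsAsFactors = FALSE)
  methods::new("TraitTable", traits = Y, covariates = cov, spec = spec)
}

#' Read gene annotation from GFF3 or BED
#'
#' GFF3 `gene` features are read as-is (1-based, closed intervals); BED
#' intervals (0-based, half-open) are converted to the 1-based closed
#' convention on ingest (both via [rtracklayer::import()]). Gene ids come
#' from the GFF3 `ID` attribute (BED name column), symbols from `Name`
#' (falling back to the id).
#'
#' @param path annotation file; format chosen by extension unless `format`
#'   is given (`"gff3"` or `"bed"`).
#' @param format optional explicit format.
#' @return gene annotation `data.frame` with columns `geneId`, `symbol`,
#'   `chrom`, `start`, `end`, `strand` (plus `module`/`isHub` when present
#'   in the GFF3 attributes).
#' @export
readGeneAnnotation <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = format)
  mc <- S4Vectors::mcols(gr)
  if (format == "bed") {
    if (is.null(mc$name)) stop("BED needs a name column for gene ids")
    ids <- mc$name; sym <- mc$name
  } else {
    keep <- !is.na(mc$type) & as.character(mc$type) == "gene"
    if (!any(keep)) stop("no 'gene' features found in ", path)
    gr <- gr[keep]; mc <- S4Vectors::mcols(gr)
    ids <- mc$ID
    sym <- if (is.null(mc$Name)) ids else ifelse(is.na(mc$Name), ids, mc$Name)
  }
  out <- data.frame(geneId = ids, symbol = sym,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(BiocGenerics::strand(gr)),
                    stringsAsFactors = FALSE)
  if (!is.null(mc$module)) out$module <- as.integer(mc$module)
  if (!is.null(mc$hub)) out$isHub <- mc$hub == "true"
  out
}

#' Read a regulator census (one gene symbol per line)
#'
#' @param path text file path; blank lines and `#` comments ignored.
#' @return character vector of symbols.
#' @export
readCensus <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a fixture ground-truth JSON
#'
#' @param path truth file written by [writeFixture()].
#' @return list with `causalMap`, `hubGenes`, `trueH2`, `effects`.
#' @export
readTruth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  eff <- j$effects$values
  dimnames(eff) <- list(j$effects$genes, j$effects$traits)
  list(causalMap = j$causalMap, hubGenes = j$hubGenes,
       trueH2 = unlist(j$trueH2), effects = eff)
}
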