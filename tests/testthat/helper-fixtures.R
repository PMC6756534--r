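# Fixture builders and independent oracles shared across the suite.
# Oracles deliberately re-derive every quantity with the dumbest possible
# method (per-record re-checks, O(n^2) window scans, whole-protein diffs)
# and never call the code path they are checking.

recDf <- function(...) data.frame(..., stringsAsFactors = FALSE)

# a small, quick simulation plan used by most bundle-based tests
smallPlan <- function(seed, ...) {
  args <- list(seed = seed, nGenes = 40L, genomeLength = 300000L,
               nTrueSnps = 150L, nEditingSites = 6L,
               violations = c(lowQD = 2L, highFS = 2L, lowDP = 2L,
                              lowMQ = 2L, lowMQRankSum = 2L,
                              lowReadPosRankSum = 2L, lowALTreads = 2L,
                              lowHet = 2L),
               nClusterGroups = 1L, nAbsentNoReads = 3L,
               nAbsentDefaultFiltered = 2L, nAbsentCustomFiltered = 5L,
               nGenotypeMismatch = 4L, nWgsOnly = 8L)
  args[names(list(...))] <- list(...)
  do.call(simulationPlan, args)
}

# random records exercising every filter threshold region, with missing
# annotations mixed in
randomFilterRecords <- function(n, seed) {
  set.seed(seed)
  chrom <- sample(paste0("chr", 1:5), n, replace = TRUE)
  pos <- sample.int(500000L, n, replace = TRUE)
  df <- recDf(chrom = chrom, pos = pos, ref = "A", alt = "G",
              genotype = "0/1",
              total_depth = sample(1:80, n, replace = TRUE))
  df$alt_depth <- pmin(df$total_depth, sample(0:60, n, replace = TRUE))
  maybe <- function(v) ifelse(stats::runif(n) < 0.15, NA, v)
  df$QD <- maybe(round(stats::runif(n, 0, 35), 2))
  df$FS <- maybe(round(stats::runif(n, 0, 90), 2))
  df$MQ <- maybe(round(stats::runif(n, 20, 70), 2))
  df$MQRankSum <- maybe(round(stats::runif(n, -20, 5), 2))
  df$ReadPosRankSum <- maybe(round(stats::runif(n, -12, 5), 2))
  df$DP <- maybe(sample(1:80, n, replace = TRUE))
  df <- df[!duplicated(paste(df$chrom, df$pos)), , drop = FALSE]
  df[order(df$chrom, df$pos), , drop = FALSE]
}

# independent per-record re-check of every site criterion
oracleSiteFailures <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    f <- character()
    if (!is.na(r$QD) && r$QD < 5) f <- c(f, "lowQD")
    if (!is.na(r$FS) && r$FS > 60) f <- c(f, "highFS")
    dp <- if (!is.na(r$DP)) r$DP else r$total_depth
    if (!is.na(dp) && dp < 10) f <- c(f, "lowDP")
    if (!is.na(r$MQ) && r$MQ < 40) f <- c(f, "lowMQ")
    if (!is.na(r$MQRankSum) && r$MQRankSum < -12.5) f <- c(f, "lowMQRankSum")
    if (!is.na(r$ReadPosRankSum) && r$ReadPosRankSum < -8)
      f <- c(f, "lowReadPosRankSum")
    if (!is.na(r$alt_depth) && r$alt_depth < 5) f <- c(f, "lowALTreads")
    if (!is.na(r$alt_depth) && !is.na(r$total_depth) && r$total_depth > 0 &&
        r$alt_depth / r$total_depth <= 0.10) f <- c(f, "lowHet")
    f
  })
}

# brute-force 3-in-35bp cluster scan: every anchored window, O(n^2)
oracleClusters <- function(df, size = 3L, win = 35L) {
  flag <- logical(nrow(df))
  for (ct in unique(df$chrom)) {
    idx <- which(df$chrom == ct)
    p <- df$pos[idx]
    for (j in seq_along(p)) {
      inwin <- which(p >= p[j] & p <= p[j] + win - 1L)
      if (length(inwin) >= size) flag[idx[inwin]] <- TRUE
    }
  }
  flag
}

# whole-protein translation diff: rebuilds the full coding sequence from an
# independently parsed GFF3, substitutes the base, translates both proteins
# and classifies the difference
oracleProteinEffect <- function(gff_path, genome, chrom, pos, alt) {
  g <- utils::read.table(gff_path, sep = "\t", comment.char = "#",
                         quote = "", stringsAsFactors = FALSE)
  names(g) <- c("chrom", "src", "type", "start", "end", "score", "strand",
                "phase", "attr")
  cds <- g[g$type == "CDS", , drop = FALSE]
  cds$tx <- sub(".*Parent=([^;]+).*", "\\1", cds$attr)
  hit <- cds$chrom == chrom & cds$start <= pos & cds$end >= pos
  if (!any(hit)) return(NULL)
  tx <- sort(unique(cds$tx[hit]))[1L]
  seg <- cds[cds$tx == tx, , drop = FALSE]
  seg <- seg[order(seg$start), , drop = FALSE]
  strand <- seg$strand[1L]
  build <- function(repl = NULL) {
    ch <- unlist(lapply(seq_len(nrow(seg)), function(k) {
      v <- strsplit(as.character(Biostrings::subseq(
        genome[[chrom]], seg$start[k], seg$end[k])), "")[[1L]]
      prange <- seg$start[k]:seg$end[k]
      if (!is.null(repl) && pos %in% prange)
        v[which(prange == pos)] <- repl
      v
    }))
    sq <- paste(ch, collapse = "")
    if (strand == "-")
      sq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sq)))
    ph <- if (strand == "-") as.integer(seg$phase[nrow(seg)])
          else as.integer(seg$phase[1L])
    substring(sq, ph + 1L)
  }
  tr <- function(sq) {
    ncod <- nchar(sq) %/% 3L
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(sq, 1L, ncod * 3L))))
  }
  p_ref <- tr(build())
  p_alt <- tr(build(alt))
  if (p_ref == p_alt) return("synonymous")
  a <- strsplit(p_ref, "")[[1L]]
  b <- strsplit(p_alt, "")[[1L]]
  d <- which(a != b)
  if (any(a[d] == "*" | b[d] == "*")) "stop_gain_loss" else "non_synonymous"
}

# toy one-gene model used across annotation tests: plus-strand gene with a
# CDS "ATG GCC TAA" split by a 3 bp intron inside the gene
writeToyGff3 <- function(path) {
  writeLines(c("##gff-version 3",
    "chr1\ttest\tgene\t91\t120\t.\t+\t.\tID=gene1",
    "chr1\ttest\tmRNA\t91\t120\t.\t+\t.\tID=tx1;Parent=gene1",
    "chr1\ttest\texon\t91\t112\t.\t+\t.\tID=e1;Parent=tx1",
    "chr1\ttest\texon\t116\t120\t.\t+\t.\tID=e2;Parent=tx1",
    "chr1\ttest\tCDS\t101\t109\t.\t+\t0\tID=c1;Parent=tx1"), path)
  path
}

writeToyGtf <- function(path) {
  writeLines(c(
    'chr1\ttest\tgene\t91\t120\t.\t+\t.\tgene_id "gene1";',
    paste0('chr1\ttest\ttranscript\t91\t120\t.\t+\t.\tgene_id "gene1"; ',
           'transcript_id "tx1";'),
    paste0('chr1\ttest\texon\t91\t112\t.\t+\t.\tgene_id "gene1"; ',
           'transcript_id "tx1";'),
    paste0('chr1\ttest\texon\t116\t120\t.\t+\t.\tgene_id "gene1"; ',
           'transcript_id "tx1";'),
    paste0('chr1\ttest\tCDS\t101\t109\t.\t+\t0\tgene_id "gene1"; ',
           'transcript_id "tx1";')), path)
  path
}

writeToyFasta <- function(path) {
  g <- paste(rep("A", 200), collapse = "")
  substr(g, 101, 109) <- "ATGGCCTAA"
  writeLines(c(">chr1", g), path)
  path
}

toyModel <- function() {
  loadGeneModel(writeToyGff3(tempfile(fileext = ".gff3")))
}

keyOf <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
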