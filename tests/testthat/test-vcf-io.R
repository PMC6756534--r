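test_that("a single-record VCF maps onto the data model field by field", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="a">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("chr1", "100", ".", "A", "G", ".", "PASS", ".", "GT:AD",
          "1/1:0,30", sep = "\t")), path)
  cs <- readSnpVcf(path, "star")
  df <- variantRecords(cs)
  expect_equal(nrow(df), 1L)
  expect_equal(df$alt_depth, 30L)
  expect_equal(df$total_depth, 30L)
  expect_equal(df$genotype, "1/1")
  expect_true(df$is_snp)
  expect_identical(sourceLabel(cs), "star")
})

test_that("multi-allelic records split per alternate allele, conserving AD", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="a">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("chr1", "100", ".", "A", "G,T", ".", "PASS", ".", "GT:AD",
          "1/2:2,10,8", sep = "\t")), path)
  df <- variantRecords(readSnpVcf(path, "x"))
  expect_equal(nrow(df), 2L)
  expect_setequal(df$alt, c("G", "T"))
  expect_equal(df$alt_depth[df$alt == "G"], 10L)
  expect_equal(df$alt_depth[df$alt == "T"], 8L)
  expect_true(all(df$total_depth == 20L))
  # split conserves the alternate entries of the AD vector
  expect_equal(sum(df$alt_depth), 18L)
})

test_that("an empty VCF body yields an empty call set", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")), path)
  expect_equal(nVariants(readSnpVcf(path, "x")), 0L)
})

test_that("indel alleles are parsed but flagged non-SNP", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("chr1", "100", ".", "AT", "A", ".", "PASS", ".", sep = "\t"),
    paste("chr1", "200", ".", "C", "T", ".", "PASS", ".", sep = "\t")), path)
  df <- variantRecords(readSnpVcf(path, "x"))
  expect_equal(df$is_snp, c(FALSE, TRUE))
})

test_that("read-write-read round trip is the identity on retained fields", {
  set.seed(42)
  for (rep in 1:3) {
    n <- sample(3:40, 1)
    df <- recDf(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                pos = sample.int(100000L, n),
                ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                genotype = sample(c("0/1", "1/1"), n, replace = TRUE),
                total_depth = sample(10:90, n, replace = TRUE))
    df$alt <- vapply(df$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    df$alt_depth <- pmin(df$total_depth, sample(5:80, n, replace = TRUE))
    df$QD <- ifelse(runif(n) < 0.3, NA, round(runif(n, 1, 30), 2))
    df <- df[!duplicated(paste(df$chrom, df$pos)), , drop = FALSE]
    cs <- callSet(df, "rt", contigs = c("chr1", "chr2"))
    path <- tempfile(fileext = ".vcf")
    writeSnpVcf(cs, path)
    back <- variantRecords(readSnpVcf(path, "rt"))
    keep <- c("chrom", "pos", "ref", "alt", "genotype", "total_depth",
              "alt_depth")
    expect_identical(back[, keep], variantRecords(cs)[, keep])
    # metrics survive too (NA stays NA, never zero)
    expect_equal(back$QD, variantRecords(cs)$QD)
    # stability: a second round trip is exact
    path2 <- tempfile(fileext = ".vcf")
    writeSnpVcf(readSnpVcf(path, "rt"), path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("verdict annotations land in the FILTER column", {
  df <- recDf(chrom = "chr1", pos = c(100L, 200L), ref = "A", alt = "G",
              genotype = "0/1", total_depth = 40L, alt_depth = 20L)
  cs <- callSet(df, "x")
  path <- tempfile(fileext = ".vcf")
  writeSnpVcf(cs, path,
              filter_annotations = list("chr1:100:A:G" = c("lowDP", "lowHet")))
  body <- grep("^chr1", readLines(path), value = TRUE)
  expect_match(body[1], "\tlowDP;lowHet\t")
  expect_match(body[2], "\tPASS\t")
  # and read back through the independent parser
  back <- variantRecords(readSnpVcf(path, "x"))
  expect_equal(back$filter, c("lowDP;lowHet", "PASS"))
})

test_that("an empty call set writes a header-only VCF", {
  path <- tempfile(fileext = ".vcf")
  writeSnpVcf(callSet(recDf(chrom = character(), pos = integer(),
                            ref = character(), alt = character()), "x",
                      contigs = "chr1"), path)
  expect_false(any(grepl("^chr1\t", readLines(path))))
  expect_equal(nVariants(readSnpVcf(path, "x")), 0L)
})

test_that("unreadable inputs raise I/O errors naming the path", {
  expect_error(readSnpVcf("/nonexistent/x.vcf", "a"), "x.vcf")
  expect_error(readDepthTrack("/nonexistent/d.tsv"), "d.tsv")
  expect_error(loadGeneModel("/nonexistent/g.gff3"), "g.gff3")
})

test_that("depth tracks read TSV positions and expand BED intervals", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tdepth", "chr1\t100\t12", "chr2\t7\t0"), tsv)
  track <- readDepthTrack(tsv)
  expect_equal(depthAt(track, "chr1", 100), 12L)
  expect_equal(depthAt(track, "chr2", 7), 0L)
  # unlisted position gets the default
  expect_equal(depthAt(track, "chr1", 101), 0L)
  expect_equal(depthAt(readDepthTrack(tsv, default_depth = 9L), "chr9", 1),
               9L)

  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t101\t7", bed)
  tb <- readDepthTrack(bed)
  # 0-based half-open [99, 101) covers 1-based positions 100 and 101
  expect_equal(depthAt(tb, "chr1", c(99, 100, 101, 102)), c(0L, 7L, 7L, 0L))

  bad <- tempfile(fileext = ".tsv")
  writeLines("chr1\t100\t-3", bad)
  expect_error(readDepthTrack(bad), "negative")
})
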