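test_that("GFF3 and GTF encodings of the same gene load identically", {
  m_gff <- loadGeneModel(writeToyGff3(tempfile(fileext = ".gff3")))
  m_gtf <- loadGeneModel(writeToyGtf(tempfile(fileext = ".gtf")))
  expect_equal(length(m_gff@genes), 1L)
  expect_equal(length(m_gff@exons), 2L)
  expect_equal(m_gff@transcripts$coding, TRUE)
  for (slot in c("genes", "exons", "cds", "utr", "introns")) {
    a <- methods::slot(m_gff, slot)
    b <- methods::slot(m_gtf, slot)
    expect_equal(BiocGenerics::start(a), BiocGenerics::start(b), info = slot)
    expect_equal(BiocGenerics::end(a), BiocGenerics::end(b), info = slot)
  }
  # derived features: UTRs are exon minus CDS, introns the exon gaps
  expect_setequal(BiocGenerics::start(m_gff@utr), c(91L, 110L, 116L))
  expect_equal(BiocGenerics::start(m_gff@introns), 113L)
  expect_equal(BiocGenerics::end(m_gff@introns), 115L)
})

test_that("a CDS without a parent transcript is rejected by name", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\ttest\tCDS\t10\t30\t.\t+\t0\tID=c1;Parent=missing_tx"), path)
  expect_error(loadGeneModel(path), "parent transcript")
})

test_that("annotation respects the category precedence on the toy gene", {
  model <- loadGeneModel(writeToyGff3(tempfile(fileext = ".gff3")))
  genome <- loadReferenceGenome(writeToyFasta(tempfile(fileext = ".fa")))
  v <- recDf(chrom = "chr1",
             pos = c(5L, 95L, 106L, 114L, 30L),
             ref = c("A", "A", "C", "A", "A"),
             alt = c("G", "G", "A", "G", "T"),
             total_depth = 30L, alt_depth = 15L)
  ann <- annotateVariants(v, model, genome)
  get <- function(p) ann$category[ann$pos == p]
  expect_equal(get(5), "upstream_downstream")   # < 1000 bp from the gene
  expect_equal(get(95), "UTR3_UTR5")
  expect_equal(get(106), "exonic")
  expect_equal(get(114), "splicing")            # 2nd base of the intron
  expect_equal(get(30), "upstream_downstream")
  expect_equal(ann$gene_id[ann$pos == 106], "gene1")
})

test_that("SNPs far from any gene are intergenic, and an empty model makes
          everything intergenic", {
  model <- loadGeneModel(writeToyGff3(tempfile(fileext = ".gff3")))
  far <- recDf(chrom = "chr9", pos = 50000L, ref = "A", alt = "G")
  expect_equal(annotateVariants(far, model)$category, "intergenic")
  empty_path <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty_path)
  empty_model <- suppressWarnings(loadGeneModel(empty_path))
  v <- recDf(chrom = "chr1", pos = c(5L, 106L), ref = "A", alt = "G")
  expect_equal(annotateVariants(v, empty_model)$category,
               c("intergenic", "intergenic"))
})

test_that("codon effects on the plus strand: synonymous and stop changes", {
  model <- loadGeneModel(writeToyGff3(tempfile(fileext = ".gff3")))
  genome <- loadReferenceGenome(writeToyFasta(tempfile(fileext = ".fa")))
  # CDS 101-109 is ATG GCC TAA
  v <- recDf(chrom = "chr1", pos = c(106L, 107L, 105L),
             ref = c("C", "T", "C"), alt = c("A", "C", "G"),
             total_depth = 30L, alt_depth = 15L)
  ann <- annotateVariants(v, model, genome)
  expect_equal(ann$effect[ann$pos == 106], "synonymous")      # GCC->GCA, Ala
  expect_equal(ann$effect[ann$pos == 107], "stop_gain_loss")  # TAA->CAA
  expect_equal(ann$aa_change[ann$pos == 107], "*/Q")
  expect_equal(ann$effect[ann$pos == 105], "non_synonymous")  # GCC->GGC, A/G
})

test_that("codon effects honour the minus strand (reverse complement)", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\ttest\tgene\t131\t160\t.\t-\t.\tID=gene2",
    "chr1\ttest\tmRNA\t131\t160\t.\t-\t.\tID=tx2;Parent=gene2",
    "chr1\ttest\texon\t131\t160\t.\t-\t.\tID=e3;Parent=tx2",
    "chr1\ttest\tCDS\t141\t149\t.\t-\t0\tID=c2;Parent=tx2"), gff)
  fa <- tempfile(fileext = ".fa")
  g <- paste(rep("A", 200), collapse = "")
  substr(g, 141, 149) <- "TTAGGCCAT"  # revcomp of ATG GCC TAA
  writeLines(c(">chr1", g), fa)
  model <- loadGeneModel(gff)
  genome <- loadReferenceGenome(fa)
  # third base of codon 2 (GCC) sits at genomic 144 on the minus strand
  ann <- annotateVariants(recDf(chrom = "chr1", pos = 144L, ref = "G",
                                alt = "T", total_depth = 30L,
                                alt_depth = 15L), model, genome)
  expect_equal(ann$category, "exonic")
  expect_equal(ann$effect, "synonymous")  # GCC->GCA on the coding strand
})

test_that("reference mismatches are reported and skipped", {
  model <- loadGeneModel(writeToyGff3(tempfile(fileext = ".gff3")))
  genome <- loadReferenceGenome(writeToyFasta(tempfile(fileext = ".fa")))
  v <- recDf(chrom = "chr1", pos = c(106L, 5L), ref = c("T", "A"),
             alt = c("A", "G"), total_depth = 30L, alt_depth = 15L)
  expect_warning(ann <- annotateVariants(v, model, genome), "reference")
  expect_true(is.na(ann$category[ann$pos == 106]))
  expect_equal(attr(ann, "reference_mismatch"), "chr1:106:T:A")
  expect_equal(ann$category[ann$pos == 5], "upstream_downstream")
})

test_that("category summary reproduces planted per-category statistics", {
  ann <- recDf(key = sprintf("chr1:%d:A:G", 1:10), chrom = "chr1", pos = 1:10,
               ref = "A", alt = "G", category = "exonic",
               effect = "synonymous", aa_change = "A/A", gene_id = "g",
               tx_id = "t")
  zyg <- recDf(key = ann$key, vaf = 1.0, zygosity = "homozygous_alt")
  cs <- categorySummary(ann, zyg)
  ex <- cs[cs$category == "exonic", ]
  expect_equal(ex$n, 10L)
  expect_equal(ex$pct, 100)
  expect_equal(ex$mean_vaf, 1.0)
  expect_equal(ex$sd_vaf, 0)
  expect_equal(ex$n_hom, 10L)
  expect_equal(ex$pct_hom, 100)
  # effect rows are sub-counts of exonic, not extra categories
  expect_equal(cs$n[cs$category == "synonymous"], 10L)
  expect_equal(cs$parent[cs$category == "synonymous"], "exonic")
  main <- cs[is.na(cs$parent), ]
  expect_equal(sum(main$n), 10L)

  expect_error(categorySummary(ann, zyg[-1, ]), "same variant keys")
  empty <- categorySummary(ann[0, ], zyg[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("a planted category mix is recovered exactly", {
  set.seed(5)
  cats <- c(rep("intergenic", 20), rep("intronic", 7), rep("exonic", 5),
            rep("UTR3_UTR5", 3))
  ann <- recDf(key = sprintf("chr1:%d:A:G", seq_along(cats)), chrom = "chr1",
               pos = seq_along(cats), ref = "A", alt = "G", category = cats,
               effect = ifelse(cats == "exonic", "non_synonymous", NA),
               aa_change = NA, gene_id = "g", tx_id = "t")
  vaf <- round(runif(length(cats), 0.3, 1), 3)
  zyg <- recDf(key = ann$key, vaf = vaf,
               zygosity = ifelse(vaf >= 0.99, "homozygous_alt",
                                 "heterozygous"))
  cs <- categorySummary(ann, zyg)
  expect_equal(cs$n[cs$category == "intergenic"], 20L)
  expect_equal(cs$pct[cs$category == "intronic"], 700 / 35)
  expect_equal(cs$n[cs$category == "non_synonymous"], 5L)
  for (cat in unique(cats)) {
    expect_equal(cs$mean_vaf[cs$category == cat], mean(vaf[cats == cat]),
                 info = cat)
    expect_equal(cs$sd_vaf[cs$category == cat], sd(vaf[cats == cat]),
                 info = cat)
  }
})
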