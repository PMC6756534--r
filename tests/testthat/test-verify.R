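mkSet <- function(pos, gt = "1/1", source = "x", alt = "G") {
  n <- length(pos)
  callSet(recDf(chrom = rep("chr1", n), pos = pos, ref = rep("A", n),
                alt = rep(alt, length.out = n),
                genotype = rep(gt, length.out = n),
                total_depth = rep(40L, n), alt_depth = rep(20L, n)), source)
}

test_that("verification statistics follow the published formulas", {
  s <- verifyStats(verified = 90, novel = 10, ts = 90, ns = 10, ds = 30)
  expect_equal(s[["precision"]], 0.9)
  expect_equal(s[["sensitivity"]], 0.9)
  expect_equal(s[["specificity"]], 0.75)
  # zero denominators are undefined, never zero
  expect_true(is.na(verifyStats(0, 0)[["precision"]]))
  expect_true(is.na(verifyStats(10, 0, ts = 0, ns = 0, ds = 0)[["sensitivity"]]))
})

test_that("verified/novel and TS/NS/DS labels follow allele and genotype
          matching", {
  rna <- mkSet(c(100L, 200L, 300L, 400L), gt = c("1/1", "1/1", "0/1", "1/1"))
  wgs <- mkSet(c(100L, 200L, 500L), gt = c("1/1", "0/1", "1/1"), "wgs")
  dbsnp <- mkSet(c(300L, 500L), source = "dbsnp")
  res <- verifyAgainst(rna, wgs, dbsnp)
  pv <- res@perVariant
  # 100: WGS genotype match -> TS; 200: genotype mismatch -> NS
  expect_equal(pv$label[pv$key == "chr1:100:A:G"], "TS")
  expect_equal(pv$label[pv$key == "chr1:200:A:G"], "NS")
  # 300: dbSNP-only (no genotype there) -> verified, TS
  expect_equal(pv$label[pv$key == "chr1:300:A:G"], "TS")
  # 400: nowhere -> novel
  expect_equal(pv$label[pv$key == "chr1:400:A:G"], "none")
  expect_equal(res@counts[["verified"]], 3L)
  expect_equal(res@counts[["novel"]], 1L)
  # DS: WGS 500 validated in dbSNP and missed by RNA
  expect_equal(res@dsKeys, "chr1:500:A:G")
  expect_equal(res@stats[["precision"]], 3 / 4)
  expect_equal(res@stats[["sensitivity"]], 2 / 3)
  expect_equal(res@stats[["specificity"]], 2 / 3)
  # partition: verified + novel covers the RNA set
  expect_equal(res@counts[["verified"]] + res@counts[["novel"]],
               nVariants(rna))
})

test_that("allele-level matching requires the same alternate allele", {
  rna <- mkSet(100L, alt = "G")
  wgs <- mkSet(100L, alt = "T", source = "wgs")
  res <- verifyAgainst(rna, wgs, mkSet(integer(), source = "dbsnp"))
  expect_equal(res@counts[["verified"]], 0L)
})

test_that("the DS universe and coverage masks restrict DNA-verified SNPs", {
  rna <- mkSet(100L)
  wgs <- mkSet(c(100L, 200L, 300L), source = "wgs")
  dbsnp <- mkSet(c(200L, 300L), source = "dbsnp")
  expect_setequal(verifyAgainst(rna, wgs, dbsnp)@dsKeys,
                  c("chr1:200:A:G", "chr1:300:A:G"))
  # universe restriction (e.g. coding SNPs only)
  res_u <- verifyAgainst(rna, wgs, dbsnp, ds_universe = "chr1:200:A:G")
  expect_equal(res_u@dsKeys, "chr1:200:A:G")
  # coverage restriction via a depth track
  cov <- depthTrack("chr1", 200L, 15L)
  res_c <- verifyAgainst(rna, wgs, dbsnp, rna_covered = cov)
  expect_equal(res_c@dsKeys, "chr1:200:A:G")
})

test_that("adding dbSNP records never decreases the verified count", {
  set.seed(17)
  rna <- mkSet(sort(sample.int(5000L, 50L)) * 10L)
  wgs <- mkSet(integer(), source = "wgs")
  keys_pool <- variantKeys(rna)
  counts <- vapply(c(0, 10, 25, 50), function(k) {
    db <- subsetRecords <- splitStr <- NULL
    pos <- as.integer(sub("chr1:(\\d+):.*", "\\1", keys_pool[seq_len(k)]))
    db <- mkSet(pos, source = "dbsnp")
    verifyAgainst(rna, wgs, db)@counts[["verified"]]
  }, 0L)
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[4], 50L)
})

test_that("an empty RNA set gives zero counts and undefined statistics", {
  res <- verifyAgainst(mkSet(integer()), mkSet(100L, source = "w"),
                       mkSet(100L, source = "d"))
  expect_equal(res@counts[["verified"]], 0L)
  expect_true(is.na(res@stats[["precision"]]))
})

test_that("absence categories are assigned in rule order", {
  depth <- depthTrack(rep("chr1", 4), c(100L, 200L, 300L, 400L),
                      c(0L, 40L, 35L, 30L))
  raw <- callSet(recDf(chrom = "chr1", pos = c(300L, 400L), ref = "A",
                       alt = "G", genotype = "0/1", total_depth = 60L,
                       alt_depth = c(30L, 5L),
                       filter = c("LowQual", "PASS")), "raw")
  filtered <- mkSet(integer(), source = "filt")
  custom <- filterCascade(callSet(recDf(chrom = "chr1", pos = 400L,
                                        ref = "A", alt = "G",
                                        genotype = "0/1", total_depth = 60L,
                                        alt_depth = 5L), "p"),
                          filterCriteria())$verdicts
  absent <- sprintf("chr1:%d:A:G", c(100L, 200L, 300L, 400L))
  rep <- categorizeAbsent(absent, raw, filtered, depth, custom)
  got <- setNames(rep$category, rep$key)
  expect_equal(unname(got["chr1:100:A:G"]), "no_reads_mapped")
  expect_equal(unname(got["chr1:200:A:G"]), "wgs_homozygous")
  expect_equal(unname(got["chr1:300:A:G"]), "wgs_het_default_filtered")
  expect_equal(unname(got["chr1:400:A:G"]), "wgs_het_custom_filtered")
  expect_equal(rep$rdd_candidate, rep$category == "wgs_homozygous")
  # categories partition the absent set
  expect_equal(nrow(rep), length(absent))
  expect_false(anyNA(rep$category))
})

test_that("a SNP present in the filtered WGS set cannot be 'absent'", {
  filtered <- mkSet(100L, source = "filt")
  depth <- depthTrack("chr1", 100L, 20L)
  expect_error(categorizeAbsent("chr1:100:A:G", filtered, filtered, depth,
                                recDf(key = character(), pass = logical())),
               "present in the filtered")
})

test_that("overlap cells are exclusive and match brute-force membership", {
  sets <- list(A = c("x", "y"), B = c("y", "z"), C = "z")
  ov <- overlapSets(sets)
  cell <- function(s) ov$count[ov$subset == s]
  expect_equal(cell("A"), 1L)       # x
  expect_equal(cell("B"), 0L)
  expect_equal(cell("C"), 0L)
  expect_equal(cell("A&B"), 1L)     # y
  expect_equal(cell("B&C"), 1L)     # z
  expect_equal(cell("A&C"), 0L)
  expect_equal(cell("A&B&C"), 0L)
  expect_equal(sum(ov$count), 3L)

  ident <- overlapSets(list(P = c("a", "b"), Q = c("a", "b")))
  expect_equal(ident$count[ident$subset == "P&Q"], 2L)
  expect_equal(sum(ident$count), 2L)

  none <- overlapSets(list(P = character(), Q = character()))
  expect_equal(sum(none$count), 0L)
})

test_that("overlap restriction by chromosome and key subset works", {
  sets <- list(A = c("chr1:1:A:G", "chr2:5:A:G"),
               B = c("chr1:1:A:G", "chr2:9:A:G"))
  ov <- overlapSets(sets, chroms = "chr1")
  expect_equal(sum(ov$count), 1L)
  expect_equal(ov$count[ov$subset == "A&B"], 1L)
  ov2 <- overlapSets(sets, restrict = "chr2:5:A:G")
  expect_equal(ov2$count[ov2$subset == "A"], 1L)
  expect_equal(sum(ov2$count), 1L)
})

test_that("the RDD table keeps non-synonymous candidates and flags A-to-I
          consistency", {
  absence <- recDf(key = c("chr1:10:A:G", "chr1:20:C:A", "chr1:30:T:C"),
                   chrom = "chr1", pos = c(10L, 20L, 30L),
                   category = "wgs_homozygous", rdd_candidate = TRUE)
  ann <- recDf(key = absence$key, chrom = "chr1", pos = absence$pos,
               ref = c("A", "C", "T"), alt = c("G", "A", "C"),
               category = "exonic",
               effect = c("non_synonymous", "non_synonymous", "synonymous"),
               aa_change = c("I/V", "P/T", "L/L"),
               gene_id = c("COG3like", "g2", "g3"), tx_id = "t")
  zyg <- recDf(key = absence$key, vaf = c(0.524, 0.7, 0.4),
               zygosity = "heterozygous")
  tab <- rddTable(absence, ann, zyg)
  # synonymous candidate excluded; both non-synonymous rows retained
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$dna_nucleotide, c("A", "C"))
  expect_equal(tab$rdd_nucleotide, c("G", "A"))
  expect_equal(tab$amino_acid_change[1], "I/V")
  expect_equal(tab$vaf_score[1], 0.524)
  expect_equal(tab$a_to_i_consistent, c(TRUE, FALSE))

  no_cand <- absence
  no_cand$category <- "no_reads_mapped"
  no_cand$rdd_candidate <- FALSE
  expect_equal(nrow(rddTable(no_cand, ann, zyg)), 0L)
})
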