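test_that("het ratio follows aa/t with errors on undefined input", {
  expect_equal(hetRatio(30, 30), 1.0)
  expect_equal(hetRatio(1, 10), 0.10)
  expect_equal(hetRatio(5, 40), 0.125)
  expect_equal(hetRatio(c(2, 5), c(20, 50)), c(0.1, 0.1))
  expect_error(hetRatio(0, 0), "undefined")
  expect_error(hetRatio(11, 10), "<=")
  expect_error(hetRatio(NA, 10), "NA")
})

test_that("site filters fail exactly the violated criteria and skip missing
          annotations", {
  crit <- filterCriteria()
  v1 <- applySiteFilters(recDf(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                               total_depth = 60L, alt_depth = 30L,
                               QD = 4.9, FS = 10, DP = 50, MQ = 60), crit)
  expect_identical(v1$failed[[1]], "lowQD")

  # all annotations absent: nothing fails site-wise
  v2 <- applySiteFilters(recDf(chrom = "chr1", pos = 1L, ref = "A",
                               alt = "G", total_depth = 40L,
                               alt_depth = 20L), crit)
  expect_length(v2$failed[[1]], 0L)

  # DP metric 9 with 4 alt reads at ratio 0.08: three distinct failures
  v3 <- applySiteFilters(recDf(chrom = "chr1", pos = 1L, ref = "A",
                               alt = "G", total_depth = 50L, alt_depth = 4L,
                               DP = 9), crit)
  expect_setequal(v3$failed[[1]], c("lowDP", "lowALTreads", "lowHet"))

  # depth falls back to total read depth when the DP annotation is absent
  v4 <- applySiteFilters(recDf(chrom = "chr1", pos = 1L, ref = "A",
                               alt = "G", total_depth = 9L, alt_depth = 6L),
                         crit)
  expect_identical(v4$failed[[1]], "lowDP")
})

test_that("threshold boundaries behave as published: het <= 0.10 fails,
          QD exactly at the cut passes", {
  mk <- function(alt, tot, ...) recDf(chrom = "chr1", pos = 1L, ref = "A",
                                      alt = "G", total_depth = tot,
                                      alt_depth = alt, ...)
  crit <- filterCriteria()
  expect_true("lowHet" %in% applySiteFilters(mk(5L, 50L), crit)$failed[[1]])
  expect_false("lowHet" %in% applySiteFilters(mk(6L, 50L), crit)$failed[[1]])
  expect_false("lowQD" %in%
                 applySiteFilters(mk(20L, 40L, QD = 5), crit)$failed[[1]])
  expect_false("highFS" %in%
                 applySiteFilters(mk(20L, 40L, FS = 60), crit)$failed[[1]])
  expect_true("lowALTreads" %in%
                applySiteFilters(mk(4L, 30L), crit)$failed[[1]])
  expect_false("lowALTreads" %in%
                 applySiteFilters(mk(5L, 30L), crit)$failed[[1]])
})

test_that("SNP clusters flag all members of windows spanning < 35 bp", {
  crit <- filterCriteria()
  df1 <- recDf(chrom = "chr1", pos = c(100L, 120L, 134L), ref = "A",
               alt = "G")
  expect_length(flagSnpClusters(df1, crit), 3L)   # span 34 < 35
  df2 <- recDf(chrom = "chr1", pos = c(100L, 120L, 136L), ref = "A",
               alt = "G")
  expect_length(flagSnpClusters(df2, crit), 0L)   # span 36
  df3 <- recDf(chrom = "chr1", pos = c(100L, 101L), ref = "A", alt = "G")
  expect_length(flagSnpClusters(df3, crit), 0L)   # below cluster size
  # members on different chromosomes never co-cluster
  df4 <- recDf(chrom = c("chr1", "chr1", "chr2"), pos = c(100L, 110L, 120L),
               ref = "A", alt = "G")
  expect_length(flagSnpClusters(df4, crit), 0L)
  # a fourth SNP inside the window is flagged with the rest
  df5 <- recDf(chrom = "chr1", pos = c(100L, 110L, 120L, 130L), ref = "A",
               alt = "G")
  expect_length(flagSnpClusters(df5, crit), 4L)
  full <- variantRecords(callSet(recDf(chrom = "chr1",
                                       pos = c(100L, 200L, 300L),
                                       ref = "A", alt = "G"), "x"))
  expect_error(flagSnpClusters(full[c(3, 1, 2), ], crit), "sorted")
})

test_that("cascade verdicts match the independent per-record oracle", {
  df <- randomFilterRecords(1500L, seed = 303L)
  res <- filterCascade(df, filterCriteria())
  expected_site <- oracleSiteFailures(df)
  cluster_flag <- oracleClusters(df)
  for (i in seq_len(nrow(df))) {
    exp_f <- c(expected_site[[i]], if (cluster_flag[i]) "SnpCluster")
    expect_setequal(res$verdicts$failed[[i]], exp_f)
  }
  expect_equal(sum(res$verdicts$pass),
               sum(lengths(expected_site) == 0L & !cluster_flag))
})

test_that("the cascade partitions its input and is idempotent on the
          passing set", {
  df <- randomFilterRecords(800L, seed = 99L)
  res <- filterCascade(df, filterCriteria())
  expect_equal(nrow(res$verdicts), nrow(df))
  expect_equal(sum(res$verdicts$pass) + sum(!res$verdicts$pass), nrow(df))
  again <- filterCascade(res$passing, filterCriteria())
  expect_equal(nrow(again$passing), nrow(res$passing))
  expect_true(all(again$verdicts$pass))
})

test_that("verdicts are invariant under permutation of the input", {
  df <- randomFilterRecords(400L, seed = 5L)
  set.seed(1)
  shuffled <- df[sample.int(nrow(df)), , drop = FALSE]
  v1 <- filterCascade(df, filterCriteria())$verdicts
  v2 <- filterCascade(shuffled, filterCriteria())$verdicts
  v2 <- v2[match(v1$key, v2$key), ]
  expect_equal(vapply(v1$failed, function(f) paste(sort(f), collapse = ";"),
                      ""),
               vapply(v2$failed, function(f) paste(sort(f), collapse = ";"),
                      ""))
})

test_that("custom criteria propagate and invalid criteria are rejected", {
  df <- recDf(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
              total_depth = 15L, alt_depth = 8L)
  strict <- filterCriteria(dp_min = 20)
  expect_identical(applySiteFilters(df, strict)$failed[[1]], "lowDP")
  expect_error(filterCriteria(cluster_size = 1), "cluster_size")
  expect_error(filterCriteria(cluster_window_bp = 0), "cluster_window")
  expect_error(filterCriteria(qd_min = Inf), "finite")
})

test_that("the audit table lists one row per variant-filter pair", {
  df <- recDf(chrom = "chr1", pos = c(1L, 2000L), ref = "A", alt = "G",
              total_depth = c(50L, 9L), alt_depth = c(25L, 4L))
  tab <- verdictTable(filterCascade(df, filterCriteria())$verdicts)
  expect_equal(tab$filter[tab$key == "chr1:1:A:G"], "PASS")
  expect_setequal(tab$filter[tab$key == "chr1:2000:A:G"],
                  c("lowDP", "lowALTreads"))
})
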