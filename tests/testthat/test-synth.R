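test_that("a no-noise plan yields identical call sets whose intersection is
          exactly the planted truth", {
  plan <- smallPlan(301L, fpRate = 0, nEditingSites = 0L,
                    violations = c(lowQD = 0L, highFS = 0L, lowDP = 0L,
                                   lowMQ = 0L, lowMQRankSum = 0L,
                                   lowReadPosRankSum = 0L, lowALTreads = 0L,
                                   lowHet = 0L),
                    nClusterGroups = 0L, nAbsentNoReads = 0L,
                    nAbsentDefaultFiltered = 0L, nAbsentCustomFiltered = 0L,
                    nTrueSnps = 100L, nGenotypeMismatch = 0L, nWgsOnly = 0L)
  out <- tempfile("bundle")
  m <- generateBundle(plan, out)
  sets <- lapply(names(m$files$rna_vcfs), function(s)
    readSnpVcf(m$files$rna_vcfs[[s]], s))
  recs <- lapply(sets, function(cs)
    variantRecords(cs)[, c("chrom", "pos", "ref", "alt", "genotype")])
  expect_identical(recs[[1]], recs[[2]])
  expect_identical(recs[[1]], recs[[3]])
  cons <- intersectCallSets(sets)
  expect_equal(nVariants(cons), 100L)
  expect_true(all(filterCascade(cons)$verdicts$pass))
})

test_that("planted violators are removed by exactly their planted
          criterion", {
  plan <- smallPlan(302L, violations = c(lowQD = 3L, highFS = 0L,
                                         lowDP = 0L, lowMQ = 0L,
                                         lowMQRankSum = 0L,
                                         lowReadPosRankSum = 0L,
                                         lowALTreads = 0L, lowHet = 10L),
                    nClusterGroups = 2L)
  m <- generateBundle(plan, tempfile("bundle"))
  sets <- lapply(names(m$files$rna_vcfs), function(s)
    readSnpVcf(m$files$rna_vcfs[[s]], s))
  res <- filterCascade(intersectCallSets(sets))
  failed <- res$verdicts[!res$verdicts$pass, ]
  got <- setNames(vapply(failed$failed, paste, "", collapse = ";"),
                  failed$key)
  planted <- m$truth[!is.na(m$truth$planted_filter), ]
  expect_setequal(names(got), planted$key)
  expect_equal(unname(got[planted$key]), planted$planted_filter)
  expect_equal(sum(got == "lowHet"), 10L)
  expect_equal(sum(got == "SnpCluster"), 6L)  # 2 groups of 3
})

test_that("identical seeds give byte-identical bundles; different seeds
          differ", {
  plan <- smallPlan(303L)
  d1 <- tempfile("b1")
  d2 <- tempfile("b2")
  generateBundle(plan, d1)
  generateBundle(plan, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  d3 <- tempfile("b3")
  generateBundle(smallPlan(304L), d3)
  expect_false(identical(readLines(file.path(d1, "truth_variants.tsv")),
                         readLines(file.path(d3, "truth_variants.tsv"))))
})

test_that("inconsistent plans are rejected up front", {
  expect_error(generateBundle(smallPlan(1L, genomeLength = 20000L),
                              tempfile()), "inconsistent plan")
  expect_error(simulationPlan(nTrueSnps = 10L, nGenotypeMismatch = 20L),
               "nGenotypeMismatch")
  expect_error(simulationPlan(fpRate = 1.5), "rates")
})

test_that("the truth table is internally consistent with the written files", {
  plan <- smallPlan(305L)
  m <- generateBundle(plan, tempfile("bundle"))
  truth <- m$truth
  # planted absence classes are exonic and dbSNP-verified (so they stay
  # "verified" despite missing from the WGS calls); editing sites are the
  # absence class that is absent from dbSNP too
  ab <- truth[truth$role %in% c("absent_no_reads", "absent_default",
                                "absent_custom"), ]
  expect_true(all(ab$category == "exonic"))
  expect_true(all(ab$in_dbsnp))
  expect_true(all(!is.na(truth$absence_category[truth$role == "editing"])))
  # editing sites are A>G on the coding strand and absent from raw WGS
  ed <- truth[truth$role == "editing", ]
  expect_true(all(!ed$in_wgs_raw))
  expect_true(all(paste0(ed$ref, ">", ed$alt) %in% c("A>G", "T>C")))
  # depth is zero exactly at the planted no-coverage positions
  depth <- readDepthTrack(m$files$depth_track)
  expect_true(all(depthAt(depth, ab$chrom[ab$absence_category ==
                                            "no_reads_mapped"],
                          ab$pos[ab$absence_category ==
                                   "no_reads_mapped"]) == 0L))
  ok_pos <- truth[is.na(truth$absence_category), ]
  expect_true(all(depthAt(depth, ok_pos$chrom, ok_pos$pos) > 0L))
  # the filtered WGS VCF is the raw set minus default and custom failures
  raw <- readSnpVcf(m$files$wgs_raw_vcf, "raw")
  filt <- readSnpVcf(m$files$wgs_filtered_vcf, "filt")
  expect_true(all(variantKeys(filt) %in% variantKeys(raw)))
  expect_setequal(variantKeys(filt),
                  truth$key[truth$in_wgs_raw & truth$wgs_default_pass &
                              !(truth$role == "absent_custom")])
})
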