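# Verification against DNA truth sets: verified/novel, TS/NS/DS labels,
# precision / sensitivity / specificity, absence categorisation for candidate
# RNA-DNA differences, and generic multi-set overlaps.

#' Cohort accuracy statistics from verification counts
#'
#' precision = verified / (verified + novel);
#' sensitivity = TS / (TS + NS);
#' specificity = TS / (TS + DS).
#' A statistic with a zero denominator is NA.
#'
#' @param verified,novel counts of filtered RNA SNPs found / not found in the
#'   DNA truth (WGS calls or dbSNP).
#' @param ts true-verified SNPs: genotype agrees with the DNA truth.
#' @param ns non-verified SNPs: position/allele matched but genotype differs.
#' @param ds DNA-verified SNPs: WGS SNPs (validated in dbSNP) the RNA set
#'   missed.
#' @return named numeric: precision, sensitivity, specificity.
#' @examples
#' verifyStats(verified = 274777, novel = 8021)[["precision"]]  # 0.9716...
#' @export
verifyStats <- function(verified, novel, ts = NA_integer_, ns = NA_integer_,
                        ds = NA_integer_) {
  ratio <- function(num, den) {
    if (any(is.na(c(num, den))) || den == 0) NA_real_ else num / den
  }
  c(precision = ratio(verified, verified + novel),
    sensitivity = ratio(ts, ts + ns),
    specificity = ratio(ts, ts + ds))
}

.keysOf <- function(x) {
  if (is(x, "CallSet") || is(x, "ConsensusSet")) variantKeys(x)
  else if (is.data.frame(x)) recordKeys(x)
  else as.character(x)
}

.genotypesOf <- function(x) {
  df <- .recordsOf(x)
  stats::setNames(normalizeGenotype(df$genotype), recordKeys(df))
}

#' Verify a filtered RNA SNP set against WGS and dbSNP truth sets
#'
#' A SNP is *verified* when its (chrom, pos, ref, alt) key matches the WGS
#' call set or the dbSNP catalogue (allele-level match; rsIDs are not used),
#' *novel* otherwise. Among verified SNPs, *TS* (true-verified) requires the
#' unphased genotype to match the WGS genotype when the site is in WGS
#' (dbSNP-only matches count as TS since dbSNP carries no genotypes), and
#' *NS* is a verified SNP whose genotype disagrees. *DS* (DNA-verified) are
#' WGS SNPs validated in dbSNP, inside the eligible universe, that the RNA
#' set missed. Because the verified/genotype question is ambiguous in mixed
#' truth sets, both `verified` (allele-level) and `verified_genotype` counts
#' are reported.
#'
#' @param rna filtered RNA consensus set ([ConsensusSet-class], CallSet or
#'   records data.frame).
#' @param wgs WGS call set ([CallSet-class]); its genotypes define TS vs NS.
#' @param dbsnp known-variant call set ([CallSet-class]), may be sites-only.
#' @param ds_universe optional keys restricting the DS universe (e.g. coding
#'   WGS SNPs); default all WGS keys.
#' @param rna_covered optional [DepthTrack-class] (RNA coverage) or character
#'   "chrom:pos" keys; when supplied, DS is further restricted to covered
#'   positions.
#' @return A [VerificationResult-class].
#' @export
verifyAgainst <- function(rna, wgs, dbsnp, ds_universe = NULL,
                          rna_covered = NULL) {
  rna_df <- .recordsOf(rna)
  rna_keys <- recordKeys(rna_df)
  rna_gt <- normalizeGenotype(rna_df$genotype)
  wgs_keys <- .keysOf(wgs)
  wgs_gt <- .genotypesOf(wgs)
  dbsnp_keys <- .keysOf(dbsnp)

  in_wgs <- rna_keys %in% wgs_keys
  in_dbsnp <- rna_keys %in% dbsnp_keys
  verified <- in_wgs | in_dbsnp

  gt_match <- rep(NA, length(rna_keys))
  gt_match[in_wgs] <- {
    w <- wgs_gt[rna_keys[in_wgs]]
    r <- rna_gt[in_wgs]
    is.na(w) | (!is.na(r) & r == w)
  }
  label <- rep("none", length(rna_keys))
  label[verified] <- "TS"
  label[in_wgs & !gt_match] <- "NS"
  verified_genotype <- sum(label == "TS")

  ds_pool <- unique(wgs_keys)
  if (!is.null(ds_universe)) ds_pool <- intersect(ds_pool,
                                                  as.character(ds_universe))
  ds_pool <- ds_pool[ds_pool %in% dbsnp_keys]
  if (!is.null(rna_covered)) {
    pk <- splitKey(ds_pool)
    covered <- if (is(rna_covered, "DepthTrack")) {
      depthAt(rna_covered, pk$chrom, pk$pos) > 0L
    } else {
      positionKey(pk$chrom, pk$pos) %in% as.character(rna_covered)
    }
    ds_pool <- ds_pool[covered]
  }
  ds_keys <- setdiff(ds_pool, rna_keys)

  counts <- c(verified = sum(verified), novel = sum(!verified),
              verified_genotype = verified_genotype,
              TS = sum(label == "TS"), NS = sum(label == "NS"),
              DS = length(ds_keys))
  stats <- verifyStats(counts[["verified"]], counts[["novel"]],
                       counts[["TS"]], counts[["NS"]], counts[["DS"]])
  new("VerificationResult",
      perVariant = data.frame(key = rna_keys, genotype = rna_gt,
                              in_wgs = in_wgs, in_dbsnp = in_dbsnp,
                              verified = verified, label = label,
                              stringsAsFactors = FALSE),
      dsKeys = ds_keys,
      counts = stats::setNames(as.integer(counts), names(counts)),
      stats = stats)
}

ABSENCE_CATEGORIES <- c("no_reads_mapped", "wgs_homozygous",
                        "wgs_het_default_filtered", "wgs_het_custom_filtered")

#' Categorise RNA SNPs absent from the filtered WGS call set
#'
#' Mutually exclusive, exhaustive explanation of why an RNA SNP has no
#' counterpart in the filtered WGS set, decided in order per SNP:
#' \enumerate{
#'   \item WGS depth at the position is 0: `no_reads_mapped`;
#'   \item not called in the raw WGS set despite coverage: `wgs_homozygous`
#'     -- the DNA carries no alternate allele, so the site is a candidate
#'     RNA-DNA difference (`rdd_candidate = TRUE`);
#'   \item called in raw WGS but failed the caller's default filters:
#'     `wgs_het_default_filtered`;
#'   \item called and default-passing but removed by the custom cascade:
#'     `wgs_het_custom_filtered`.
#' }
#'
#' @param absent keys (or container) of RNA SNPs absent from the filtered
#'   WGS set; supplying a SNP that is present there is an error.
#' @param wgs_raw raw WGS [CallSet-class] whose records carry the caller's
#'   FILTER status.
#' @param wgs_filtered filtered WGS [CallSet-class].
#' @param wgs_depth [DepthTrack-class] of WGS read depth.
#' @param custom_verdicts verdicts data.frame from running [filterCascade()]
#'   on the default-passing raw WGS records.
#' @return data.frame: key, chrom, pos, category, rdd_candidate.
#' @export
categorizeAbsent <- function(absent, wgs_raw, wgs_filtered, wgs_depth,
                             custom_verdicts) {
  keys <- unique(.keysOf(absent))
  filt_keys <- .keysOf(wgs_filtered)
  if (any(keys %in% filt_keys))
    stop("variant(s) passed as absent are present in the filtered WGS set: ",
         paste(utils::head(intersect(keys, filt_keys), 3L), collapse = ", "))
  if (!length(keys)) {
    return(data.frame(key = character(), chrom = character(), pos = integer(),
                      category = character(), rdd_candidate = logical(),
                      stringsAsFactors = FALSE))
  }
  parts <- splitKey(keys)
  raw_df <- .recordsOf(wgs_raw)
  raw_keys <- recordKeys(raw_df)
  raw_filter <- stats::setNames(raw_df$filter, raw_keys)
  custom_failed <- custom_verdicts$key[!custom_verdicts$pass]

  depth <- depthAt(wgs_depth, parts$chrom, parts$pos)
  in_raw <- keys %in% raw_keys
  default_fail <- in_raw & !is.na(raw_filter[keys]) &
    raw_filter[keys] != "PASS"
  custom_fail <- keys %in% custom_failed

  category <- ifelse(depth == 0L, "no_reads_mapped",
               ifelse(!in_raw, "wgs_homozygous",
                ifelse(default_fail, "wgs_het_default_filtered",
                 ifelse(custom_fail, "wgs_het_custom_filtered",
                        NA_character_))))
  if (anyNA(category))
    stop("absent SNP ", keys[which(is.na(category))[1L]],
         " passed both default and custom WGS filters; inconsistent inputs")
  data.frame(key = keys, chrom = parts$chrom, pos = parts$pos,
             category = category,
             rdd_candidate = category == "wgs_homozygous",
             stringsAsFactors = FALSE)
}

#' Exclusive overlap counts across labelled variant-key sets
#'
#' Venn-style cells: for every non-empty subset of labels, the number of
#' keys belonging to exactly that subset. Cells sum to the size of the union.
#'
#' @param labeled_sets named list of character key vectors (or containers).
#' @param chroms optional chromosome names; keys on other chromosomes are
#'   dropped first (e.g. restrict to autosomes).
#' @param restrict optional key vector (e.g. exonic keys) intersected with
#'   every set first.
#' @return data.frame: subset, n_sets, count.
#' @export
overlapSets <- function(labeled_sets, chroms = NULL, restrict = NULL) {
  stopifnot(length(labeled_sets) >= 2L, !is.null(names(labeled_sets)))
  sets <- lapply(labeled_sets, .keysOf)
  if (!is.null(chroms)) {
    sets <- lapply(sets, function(k) k[splitKey(k)$chrom %in% chroms])
  }
  if (!is.null(restrict)) {
    sets <- lapply(sets, intersect, as.character(restrict))
  }
  patternCounts(sets)
}

#' Table of potentially functional RNA-DNA difference candidates
#'
#' One row per non-synonymous candidate among the `wgs_homozygous` absent
#' SNPs (the DNA is homozygous reference while the RNA carries an alternate
#' allele). A>G and T>C substitutions are flagged as consistent with A-to-I
#' editing read on the transcribed strand. Synonymous candidates remain
#' counted in the absence report but are excluded here.
#'
#' @param absence_report output of [categorizeAbsent()].
#' @param annotations output of [annotateVariants()] covering the candidates.
#' @param zygosity output of [classifyZygosity()] covering the candidates.
#' @return data.frame sorted by (chrom, pos): chrom, pos, dna_nucleotide,
#'   rdd_nucleotide, amino_acid_change, gene_short_name, vaf_score,
#'   a_to_i_consistent.
#' @export
rddTable <- function(absence_report, annotations, zygosity) {
  cand <- absence_report$key[absence_report$rdd_candidate]
  ann <- annotations[annotations$key %in% cand &
                       !is.na(annotations$effect) &
                       annotations$effect == "non_synonymous", , drop = FALSE]
  if (!nrow(ann)) {
    return(data.frame(chrom = character(), pos = integer(),
                      dna_nucleotide = character(),
                      rdd_nucleotide = character(),
                      amino_acid_change = character(),
                      gene_short_name = character(), vaf_score = numeric(),
                      a_to_i_consistent = logical(), stringsAsFactors = FALSE))
  }
  vaf <- stats::setNames(zygosity$vaf, zygosity$key)
  out <- data.frame(chrom = ann$chrom, pos = ann$pos,
                    dna_nucleotide = ann$ref, rdd_nucleotide = ann$alt,
                    amino_acid_change = ann$aa_change,
                    gene_short_name = ann$gene_id,
                    vaf_score = unname(vaf[ann$key]),
                    a_to_i_consistent = paste0(ann$ref, ">", ann$alt) %in%
                      c("A>G", "T>C"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
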