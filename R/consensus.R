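# Multi-aligner consensus: intersect per-aligner call sets at allele level.
#
# Matching key is (chrom, pos, ref, alt); the same position with a different
# alternate allele is NOT a match. Genotype disagreement between supporting
# sources does not break consensus but is flagged (and can optionally demote
# the record).

#' Intersect call sets into consensus variants
#'
#' Returns the variants whose (chrom, pos, ref, alt) key appears in at least
#' `min_support` of the input call sets. With the default
#' `min_support = length(callsets)` this is the full intersection -- the
#' published workflow keeps only SNPs found by all aligners, weighted equally.
#' `min_support = 1` yields the deduplicated union.
#'
#' @param callsets list of [CallSet-class] objects with distinct source labels.
#' @param min_support integer in `[1, length(callsets)]`.
#' @param snp_only drop non-SNP records before intersecting (default TRUE;
#'   the downstream statistics are defined for SNPs only).
#' @param representative how to pick the record whose depths/metrics drive
#'   filtering: `"first"` (record from the first-listed supporting source) or
#'   `"worst"` (per-metric minimum of QD/MQ/rank sums and DP, maximum of FS,
#'   across supporters; depths/genotype still from the first supporter).
#' @param require_concordant drop consensus variants whose supporting sources
#'   disagree on the unphased genotype (default FALSE: flag, keep).
#' @return A [ConsensusSet-class] sorted by (chrom, pos).
#' @examples
#' a <- callSet(data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "G",
#'                         genotype = "1/1", total_depth = 30, alt_depth = 30),
#'              "tophat")
#' b <- callSet(variantRecords(a), "hisat")
#' cons <- intersectCallSets(list(a, b))
#' nVariants(cons)
#' @export
intersectCallSets <- function(callsets, min_support = length(callsets),
                              snp_only = TRUE,
                              representative = c("first", "worst"),
                              require_concordant = FALSE) {
  representative <- match.arg(representative)
  stopifnot(length(callsets) >= 1L,
            all(vapply(callsets, is, TRUE, "CallSet")))
  sources <- vapply(callsets, sourceLabel, "")
  if (anyDuplicated(sources)) stop("call-set source labels must be distinct")
  ns <- length(callsets)
  if (length(min_support) != 1L || is.na(min_support) ||
      min_support < 1L || min_support > ns)
    stop("min_support must be between 1 and ", ns)
  min_support <- as.integer(min_support)

  recs <- lapply(callsets, function(cs) {
    df <- variantRecords(cs)
    if (snp_only) df <- df[df$is_snp, , drop = FALSE]
    df
  })
  keysPer <- lapply(recs, recordKeys)
  allKeys <- unique(unlist(keysPer, use.names = FALSE))
  if (!length(allKeys)) {
    df <- cbind(emptyRecords()[, c("chrom", "pos", "ref", "alt", "genotype",
                                   "total_depth", "alt_depth", METRIC_COLS)],
                data.frame(support = integer(), concordant = logical()))
    df$sources <- list()
    df$genotypes <- list()
    return(new("ConsensusSet", records = df, sourcesAll = sources,
               minSupport = min_support))
  }
  hit <- vapply(keysPer, function(k) match(allKeys, k),
                integer(length(allKeys)))
  if (length(allKeys) == 1L) hit <- matrix(hit, nrow = 1L)
  support <- rowSums(!is.na(hit))
  keep <- support >= min_support
  if (!any(keep)) {
    return(intersectCallSets(lapply(callsets, function(cs)
      callSet(emptyRecords(), sourceLabel(cs))), min_support, snp_only,
      representative, require_concordant))
  }
  hit <- hit[keep, , drop = FALSE]
  support <- as.integer(support[keep])

  nk <- nrow(hit)
  # representative record: first supporting source in input order
  firstSrc <- apply(!is.na(hit), 1L, which.max)
  parts <- lapply(seq_len(ns), function(j) {
    rows_j <- which(firstSrc == j)
    if (!length(rows_j)) return(NULL)
    cbind(.ord = rows_j,
          recs[[j]][hit[rows_j, j], , drop = FALSE])
  })
  df <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  df <- df[order(df$.ord), , drop = FALSE]
  df$.ord <- NULL
  rownames(df) <- NULL

  # per-source genotypes (normalised), in input source order
  gmat <- vapply(seq_len(ns), function(j) {
    g <- rep(NA_character_, nk)
    ok <- !is.na(hit[, j])
    g[ok] <- recs[[j]]$genotype[hit[ok, j]]
    g
  }, character(nk))
  if (nk == 1L) gmat <- matrix(gmat, nrow = 1L)
  gts <- lapply(seq_len(nk), function(i) {
    s <- !is.na(hit[i, ])
    stats::setNames(gmat[i, s], sources[s])
  })
  concordant <- apply(gmat, 1L, function(g) {
    u <- unique(g[!is.na(g)])
    length(u) <= 1L
  })

  if (representative == "worst") {
    pick <- function(col, fun) {
      vapply(seq_len(nk), function(i) {
        s <- which(!is.na(hit[i, ]))
        v <- vapply(s, function(j) recs[[j]][[col]][hit[i, j]], 0)
        v <- v[!is.na(v)]
        if (length(v)) fun(v) else NA_real_
      }, 0)
    }
    df$QD <- pick("QD", min)
    df$MQ <- pick("MQ", min)
    df$MQRankSum <- pick("MQRankSum", min)
    df$ReadPosRankSum <- pick("ReadPosRankSum", min)
    df$FS <- pick("FS", max)
    df$DP <- pick("DP", min)
  }

  df <- df[, c("chrom", "pos", "ref", "alt", "genotype",
               "total_depth", "alt_depth", METRIC_COLS)]
  df$support <- support
  df$concordant <- concordant
  df$sources <- lapply(seq_len(nk), function(i) sources[!is.na(hit[i, ])])
  df$genotypes <- gts

  if (require_concordant) df <- df[df$concordant, , drop = FALSE]
  o <- order(match(df$chrom, sort(unique(df$chrom))), df$pos, df$ref, df$alt)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  new("ConsensusSet", records = df, sourcesAll = sources,
      minSupport = min_support)
}

#' Venn-style support matrix across call sets
#'
#' Counts, for every non-empty subset of sources, the variants private to
#' exactly that subset. The cells are exclusive and sum to the size of the
#' union of all call sets.
#'
#' @param callsets list of >= 2 [CallSet-class] objects.
#' @param snp_only drop non-SNP records first (default TRUE).
#' @return data.frame with columns subset (e.g. `"tophat&star"`), n_sets and
#'   count.
#' @export
supportMatrix <- function(callsets, snp_only = TRUE) {
  stopifnot(length(callsets) >= 2L,
            all(vapply(callsets, is, TRUE, "CallSet")))
  sources <- vapply(callsets, sourceLabel, "")
  if (anyDuplicated(sources)) stop("call-set source labels must be distinct")
  sets <- lapply(callsets, function(cs) {
    df <- variantRecords(cs)
    if (snp_only) df <- df[df$is_snp, , drop = FALSE]
    recordKeys(df)
  })
  names(sets) <- sources
  patternCounts(sets)
}
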