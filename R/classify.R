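# VAF-based zygosity classification and substitution-spectrum statistics.

#' Classify zygosity from variant allele frequency
#'
#' VAF is the number of reads supporting the variant allele divided by the
#' total reads at the site (the representative record's depths). A site is
#' homozygous-alternate when VAF >= 0.99 (inclusive boundary), heterozygous
#' otherwise.
#'
#' @param x a [ConsensusSet-class], [CallSet-class] or data.frame with
#'   chrom, pos, ref, alt, alt_depth, total_depth.
#' @param hom_threshold VAF at or above which a call is homozygous-alternate
#'   (default 0.99).
#' @return data.frame with key, vaf and zygosity
#'   (`"homozygous_alt"`/`"heterozygous"`).
#' @examples
#' df <- data.frame(chrom = "chr1", pos = c(1, 2), ref = "A", alt = "G",
#'                  total_depth = c(100, 100), alt_depth = c(99, 49))
#' classifyZygosity(df)$zygosity
#' @export
classifyZygosity <- function(x, hom_threshold = 0.99) {
  df <- .recordsOf(x)
  if (!nrow(df)) {
    return(data.frame(key = character(), vaf = numeric(),
                      zygosity = character(), stringsAsFactors = FALSE))
  }
  if (any(is.na(df$total_depth)) || any(df$total_depth == 0L))
    stop("VAF is undefined at sites with zero or missing total depth")
  vaf <- hetRatio(df$alt_depth, df$total_depth)
  data.frame(key = recordKeys(df), vaf = vaf,
             zygosity = ifelse(vaf >= hom_threshold,
                               "homozygous_alt", "heterozygous"),
             stringsAsFactors = FALSE)
}

#' Substitution spectrum of a SNP set
#'
#' Counts the 12 ref>alt substitution classes, transitions (A<->G, C<->T),
#' transversions, the ts/tv ratio and the A>G + T>C share -- the excess of
#' which over the other transitions is the canonical footprint of A-to-I RNA
#' editing read as A>G on the transcribed strand. The A>G + T>C share is
#' reported against both denominators (all SNPs and transitions only).
#'
#' @param x a [ConsensusSet-class], [CallSet-class] or data.frame with
#'   chrom, pos, ref, alt; all records must be SNPs.
#' @param collapse merge reverse-complement class pairs into 6 classes
#'   (default FALSE: A>G and T>C are counted separately).
#' @return A [SpectrumSummary-class]. `tstv` is `Inf` for a transversion-free
#'   non-empty set and NA for an empty one.
#' @examples
#' df <- data.frame(chrom = "chr1", pos = 1:4, ref = c("A", "A", "A", "A"),
#'                  alt = c("G", "G", "G", "C"))
#' substitutionSpectrum(df)@tstv  # 3 transitions / 1 transversion
#' @export
substitutionSpectrum <- function(x, collapse = FALSE) {
  df <- .recordsOf(x)
  if (nrow(df) && !all(isSnpVec(df$ref, df$alt)))
    stop("substitution spectrum is defined for SNP records only")
  cls <- paste0(df$ref, ">", df$alt)
  counts <- table(factor(cls, levels = SUB_CLASSES))
  counts <- stats::setNames(as.integer(counts), SUB_CLASSES)
  ts <- sum(counts[TRANSITIONS])
  tv <- sum(counts) - ts
  total <- ts + tv
  tstv <- if (total == 0L) NA_real_ else if (tv == 0L) Inf else ts / tv
  agtc <- sum(counts[c("A>G", "T>C")])
  out_counts <- counts
  if (collapse) {
    rc <- c(A = "T", C = "G", G = "C", T = "A")
    pair <- vapply(SUB_CLASSES, function(k) {
      r <- substr(k, 1L, 1L); a <- substr(k, 3L, 3L)
      paste(sort(c(k, paste0(rc[[r]], ">", rc[[a]])))[1L])
    }, "")
    out_counts <- vapply(split(counts, pair), sum, 0L)
  }
  new("SpectrumSummary",
      counts = out_counts,
      transitions = as.integer(ts), transversions = as.integer(tv),
      tstv = tstv,
      transition_fraction = if (total) ts / total else NA_real_,
      agtc_fraction_all = if (total) agtc / total else NA_real_,
      agtc_fraction_ts = if (ts) agtc / ts else NA_real_,
      collapsed = collapse)
}

#' Flatten a SpectrumSummary to a one-row data.frame
#' @param spectrum a [SpectrumSummary-class].
#' @return data.frame with one column per class count plus the summary
#'   statistics; convenient for TSV/JSON export.
#' @export
spectrumTable <- function(spectrum) {
  stopifnot(is(spectrum, "SpectrumSummary"))
  cnt <- as.list(spectrum@counts)
  names(cnt) <- gsub(">", "_", names(cnt), fixed = TRUE)
  data.frame(c(cnt,
               list(transitions = spectrum@transitions,
                    transversions = spectrum@transversions,
                    tstv = spectrum@tstv,
                    transition_fraction = spectrum@transition_fraction,
                    agtc_fraction_all = spectrum@agtc_fraction_all,
                    agtc_fraction_ts = spectrum@agtc_fraction_ts)),
             check.names = FALSE)
}
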