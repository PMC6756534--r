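#' @import methods
NULL

# ---------------------------------------------------------------------------
# CallSet

#' CallSet: one aligner-derived collection of variant records
#'
#' A `CallSet` holds the SNP (and non-SNP) records of a single VCF call set,
#' normalised to one alternate allele per record. Records are kept sorted by
#' (contig, position, ref, alt) and are unique on that key.
#'
#' @slot source single label naming the originating call set (aligner name).
#' @slot records data.frame with columns chrom, pos (1-based), ref, alt,
#'   genotype (unphased, e.g. "0/1"), total_depth, alt_depth, the caller
#'   annotation metrics QD, FS, MQ, MQRankSum, ReadPosRankSum, DP (NA when
#'   absent), is_snp and filter (original FILTER string, NA when missing).
#' @slot contigs character vector of contig names from the header; may carry
#'   a "lengths" attribute (named integer vector).
#'
#' @seealso [readSnpVcf()], [writeSnpVcf()], [intersectCallSets()]
#' @export
setClass("CallSet",
         representation(source = "character",
                        records = "data.frame",
                        contigs = "character"))

setValidity("CallSet", function(object) {
  msg <- character()
  if (length(object@source) != 1L || is.na(object@source))
    msg <- c(msg, "source must be a single non-NA label")
  df <- object@records
  miss <- setdiff(RECORD_COLS, names(df))
  if (length(miss))
    msg <- c(msg, paste("records missing columns:", paste(miss, collapse = ", ")))
  if (!length(msg) && nrow(df)) {
    if (any(df$pos < 1L, na.rm = TRUE)) msg <- c(msg, "pos must be >= 1")
    if (any(df$ref == df$alt, na.rm = TRUE)) msg <- c(msg, "alt must differ from ref")
    bad_ad <- !is.na(df$alt_depth) & !is.na(df$total_depth) &
      df$alt_depth > df$total_depth
    if (any(bad_ad)) msg <- c(msg, "alt_depth must be <= total_depth")
    if (anyDuplicated(recordKeys(df)))
      msg <- c(msg, "duplicate (chrom, pos, ref, alt) records")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CallSet from a data.frame of variant records
#'
#' @param records data.frame with at least chrom, pos, ref, alt; optional
#'   genotype, total_depth, alt_depth and annotation metric columns.
#' @param source label of the originating call set.
#' @param contigs optional contig names (ordering authority for sorting).
#' @return A [CallSet-class] object, records sorted and validated.
#' @examples
#' cs <- callSet(data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "G",
#'                          genotype = "1/1", total_depth = 30, alt_depth = 30),
#'               source = "star")
#' nVariants(cs)
#' @export
callSet <- function(records, source, contigs = character()) {
  new("CallSet", source = source, records = asRecords(records, contigs),
      contigs = contigs)
}

# ---------------------------------------------------------------------------
# ConsensusSet

#' ConsensusSet: variants supported by multiple call sets
#'
#' Result of [intersectCallSets()]. Each row is one consensus variant keyed by
#' (chrom, pos, ref, alt) with the per-source support it received and the
#' representative record whose depths/metrics drive downstream filtering.
#'
#' @slot records data.frame of representative records plus `support` (number
#'   of supporting call sets), `concordant` (TRUE iff all supporting sources
#'   report the same unphased genotype) and list-columns `sources` and
#'   `genotypes` (per supporting source, in call-set order).
#' @slot sourcesAll labels of all input call sets, in input order.
#' @slot minSupport the support threshold the set was built with.
#' @export
setClass("ConsensusSet",
         representation(records = "data.frame",
                        sourcesAll = "character",
                        minSupport = "integer"))

setValidity("ConsensusSet", function(object) {
  df <- object@records
  need <- c("chrom", "pos", "ref", "alt", "genotype", "total_depth",
            "alt_depth", METRIC_COLS, "support", "concordant",
            "sources", "genotypes")
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(paste("records missing columns:", paste(miss, collapse = ", ")))
  if (nrow(df) && any(df$support < 1L)) return("support must be >= 1")
  TRUE
})

# ---------------------------------------------------------------------------
# FilterCriteria

#' FilterCriteria: thresholds of the hard + custom filter cascade
#'
#' Defaults are the published cascade: QD < 5, FS > 60, DP < 10, MQ < 40,
#' MQRankSum < -12.5, ReadPosRankSum < -8, >= 3 SNPs in a 35 bp window,
#' alternate-supporting reads < 5, and alternate-allele ratio aa/t <= 0.10
#' (the ratio threshold is inclusive: exactly 0.10 fails).
#'
#' @slot qd_min,fs_max,dp_min,mq_min,mqranksum_min,readpos_ranksum_min numeric
#'   site-level thresholds.
#' @slot cluster_size,cluster_window_bp SNP-cluster rule (>= cluster_size SNPs
#'   spanning < cluster_window_bp bases).
#' @slot alt_reads_min minimum reads supporting the alternate allele.
#' @slot het_ratio_min alternate-allele ratio threshold (fail when <=).
#' @export
setClass("FilterCriteria",
         representation(qd_min = "numeric", fs_max = "numeric",
                        dp_min = "numeric", mq_min = "numeric",
                        mqranksum_min = "numeric",
                        readpos_ranksum_min = "numeric",
                        cluster_size = "integer",
                        cluster_window_bp = "integer",
                        alt_reads_min = "numeric",
                        het_ratio_min = "numeric"))

setValidity("FilterCriteria", function(object) {
  msg <- character()
  vals <- c(object@qd_min, object@fs_max, object@dp_min, object@mq_min,
            object@mqranksum_min, object@readpos_ranksum_min,
            object@alt_reads_min, object@het_ratio_min)
  if (any(!is.finite(vals))) msg <- c(msg, "all thresholds must be finite")
  if (length(object@cluster_size) != 1L || is.na(object@cluster_size) ||
      object@cluster_size < 2L)
    msg <- c(msg, "cluster_size must be >= 2")
  if (length(object@cluster_window_bp) != 1L ||
      is.na(object@cluster_window_bp) || object@cluster_window_bp < 1L)
    msg <- c(msg, "cluster_window_bp must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct filter criteria
#'
#' @param qd_min fail lowQD when QD < qd_min (default 5).
#' @param fs_max fail highFS when FS > fs_max (default 60).
#' @param dp_min fail lowDP when depth < dp_min (default 10).
#' @param mq_min fail lowMQ when MQ < mq_min (default 40).
#' @param mqranksum_min fail lowMQRankSum when MQRankSum < -12.5.
#' @param readpos_ranksum_min fail lowReadPosRankSum when ReadPosRankSum < -8.
#' @param cluster_size,cluster_window_bp SnpCluster rule: >= cluster_size SNPs
#'   whose positions span fewer than cluster_window_bp bases (default 3 / 35).
#' @param alt_reads_min fail lowALTreads when alt-supporting reads < 5.
#' @param het_ratio_min fail lowHet when aa/t <= 0.10 (inclusive).
#' @return A validated [FilterCriteria-class] object.
#' @examples
#' filterCriteria()
#' filterCriteria(dp_min = 20)
#' @export
filterCriteria <- function(qd_min = 5, fs_max = 60, dp_min = 10, mq_min = 40,
                           mqranksum_min = -12.5, readpos_ranksum_min = -8,
                           cluster_size = 3L, cluster_window_bp = 35L,
                           alt_reads_min = 5, het_ratio_min = 0.10) {
  new("FilterCriteria", qd_min = qd_min, fs_max = fs_max, dp_min = dp_min,
      mq_min = mq_min, mqranksum_min = mqranksum_min,
      readpos_ranksum_min = readpos_ranksum_min,
      cluster_size = as.integer(cluster_size),
      cluster_window_bp = as.integer(cluster_window_bp),
      alt_reads_min = alt_reads_min, het_ratio_min = het_ratio_min)
}

# ---------------------------------------------------------------------------
# DepthTrack

#' DepthTrack: per-position read depth with a default for unlisted positions
#'
#' @slot depths named integer vector; names are "chrom:pos" (1-based).
#' @slot default_depth depth assumed for positions not listed.
#' @seealso [readDepthTrack()], [depthAt()]
#' @export
setClass("DepthTrack",
         representation(depths = "integer", default_depth = "integer"))

setValidity("DepthTrack", function(object) {
  msg <- character()
  if (length(object@depths) && any(object@depths < 0L, na.rm = TRUE))
    msg <- c(msg, "depths must be >= 0")
  if (length(object@default_depth) != 1L || is.na(object@default_depth) ||
      object@default_depth < 0L)
    msg <- c(msg, "default_depth must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a DepthTrack from vectors
#' @param chrom,pos,depth parallel vectors of per-position depth (pos 1-based).
#' @param default_depth depth assumed for unlisted positions (default 0).
#' @return A [DepthTrack-class].
#' @export
depthTrack <- function(chrom = character(), pos = integer(),
                       depth = integer(), default_depth = 0L) {
  d <- as.integer(depth)
  names(d) <- positionKey(as.character(chrom), as.integer(pos))
  new("DepthTrack", depths = d, default_depth = as.integer(default_depth))
}

# ---------------------------------------------------------------------------
# GeneModel

#' GeneModel: interval-indexed gene/transcript/CDS/UTR features
#'
#' Built by [loadGeneModel()] from GFF3 or GTF. Coordinates are 1-based
#' inclusive throughout. UTRs are derived as exon minus CDS per coding
#' transcript, and introns as gaps between exons, so both dialects yield the
#' same model whether or not they carry explicit UTR features.
#'
#' @slot genes GRanges with metadata gene_id.
#' @slot transcripts data.frame tx_id, gene_id, strand, coding.
#' @slot exons,cds,utr,introns GRanges with metadata tx_id, gene_id
#'   (cds additionally carries phase).
#' @export
setClass("GeneModel",
         representation(genes = "GRanges", transcripts = "data.frame",
                        exons = "GRanges", cds = "GRanges",
                        utr = "GRanges", introns = "GRanges"))

# ---------------------------------------------------------------------------
# SpectrumSummary

#' SpectrumSummary: substitution-class counts and transition statistics
#'
#' @slot counts named integer vector over the 12 ref>alt classes (or 6 when
#'   collapsed onto reverse-complement pairs).
#' @slot transitions,transversions counts of transition / transversion SNPs.
#' @slot tstv transitions/transversions; `Inf` when there are transitions but
#'   no transversions; NA for an empty set.
#' @slot transition_fraction transitions / total SNPs.
#' @slot agtc_fraction_all fraction of all SNPs that are A>G or T>C.
#' @slot agtc_fraction_ts fraction of transitions that are A>G or T>C.
#' @slot collapsed TRUE when reverse-complement classes were merged.
#' @seealso [substitutionSpectrum()]
#' @export
setClass("SpectrumSummary",
         representation(counts = "integer", transitions = "integer",
                        transversions = "integer", tstv = "numeric",
                        transition_fraction = "numeric",
                        agtc_fraction_all = "numeric",
                        agtc_fraction_ts = "numeric",
                        collapsed = "logical"))

# ---------------------------------------------------------------------------
# VerificationResult

#' VerificationResult: truth-set verification of a filtered RNA call set
#'
#' @slot perVariant data.frame: key, genotype, in_wgs, in_dbsnp, verified
#'   (allele-level match in WGS or dbSNP), label (TS/NS/none).
#' @slot dsKeys keys of DNA-verified SNPs (WGS SNPs validated in dbSNP,
#'   in the eligible universe, missed by RNA).
#' @slot counts named integer: verified, novel, verified_genotype, TS, NS, DS.
#' @slot stats named numeric: precision, sensitivity, specificity (NA when a
#'   denominator is zero).
#' @seealso [verifyAgainst()], [verifyStats()]
#' @export
setClass("VerificationResult",
         representation(perVariant = "data.frame", dsKeys = "character",
                        counts = "integer", stats = "numeric"))

# ---------------------------------------------------------------------------
# SimulationPlan

#' SimulationPlan: the stated world of the synthetic-data generator
#'
#' All counts are planted exactly; the same seed yields a byte-identical
#' bundle. See the methods vignette for the rationale behind each default.
#'
#' @slot seed RNG seed for the whole bundle.
#' @slot nGenes number of genes (roughly 10\% are non-coding RNA genes).
#' @slot genomeLength total genome length, split over two contigs.
#' @slot nTrueSnps clean true SNPs shared by all aligner call sets and present
#'   in the DNA truth.
#' @slot fpRate per-source private false-positive calls as a fraction of
#'   nTrueSnps.
#' @slot fractionHeterozygous fraction of true SNPs planted heterozygous
#'   (default 0.064, the observed heterozygous share in the study organism).
#' @slot violations named integer vector over the eight site filters: extra
#'   records planted to fail exactly that criterion.
#' @slot nClusterGroups extra groups of 3 SNPs within one 35 bp window.
#' @slot nEditingSites RNA-only A>G (coding-strand) edited sites, absent from
#'   DNA: the planted novel / RNA-DNA-difference class.
#' @slot rnaMeanDepth,wgsMeanDepth mean read depth for RNA / WGS records.
#' @slot nAbsentNoReads,nAbsentDefaultFiltered,nAbsentCustomFiltered planted
#'   exonic RNA SNPs absent from the filtered WGS set because of zero WGS
#'   coverage / caller default filters / the custom cascade.
#' @slot dbsnpInclusionRate fraction of true SNPs present in the dbSNP-style
#'   catalogue.
#' @slot nGenotypeMismatch true SNPs whose WGS genotype differs from the RNA
#'   genotype (the planted NS class).
#' @slot nWgsOnly WGS-only exonic SNPs in unexpressed genes (the planted DS
#'   class).
#' @slot categoryMix named numeric over annotation categories; fractions of
#'   nTrueSnps planted per category.
#' @export
setClass("SimulationPlan",
         representation(seed = "integer", nGenes = "integer",
                        genomeLength = "integer", nTrueSnps = "integer",
                        fpRate = "numeric", fractionHeterozygous = "numeric",
                        violations = "integer", nClusterGroups = "integer",
                        nEditingSites = "integer",
                        rnaMeanDepth = "integer", wgsMeanDepth = "integer",
                        nAbsentNoReads = "integer",
                        nAbsentDefaultFiltered = "integer",
                        nAbsentCustomFiltered = "integer",
                        dbsnpInclusionRate = "numeric",
                        nGenotypeMismatch = "integer",
                        nWgsOnly = "integer",
                        categoryMix = "numeric"))

setValidity("SimulationPlan", function(object) {
  msg <- character()
  rates <- c(object@fpRate, object@fractionHeterozygous,
             object@dbsnpInclusionRate)
  if (any(rates < 0 | rates > 1)) msg <- c(msg, "rates must be in [0, 1]")
  counts <- c(object@nGenes, object@genomeLength, object@nTrueSnps,
              object@violations, object@nClusterGroups, object@nEditingSites,
              object@nAbsentNoReads, object@nAbsentDefaultFiltered,
              object@nAbsentCustomFiltered, object@nGenotypeMismatch,
              object@nWgsOnly)
  if (any(is.na(counts)) || any(counts < 0L))
    msg <- c(msg, "counts must be >= 0")
  if (!setequal(names(object@violations), SITE_FILTERS))
    msg <- c(msg, "violations must be named by the eight site filters")
  if (is.null(names(object@categoryMix)) ||
      !all(names(object@categoryMix) %in% ANNOTATION_CATEGORIES))
    msg <- c(msg, "categoryMix must be named by annotation categories")
  if (abs(sum(object@categoryMix) - 1) > 1e-6)
    msg <- c(msg, "categoryMix must sum to 1")
  if (object@nGenotypeMismatch > object@nTrueSnps)
    msg <- c(msg, "nGenotypeMismatch cannot exceed nTrueSnps")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation plan
#'
#' Defaults mirror the study's stated world where it states one (6.4\%
#' heterozygous SNPs, absence categories in the reported 8.7 : 12 : 24.5 :
#' 54.8 proportions, annotation categories in the reported mix); sizes with no
#' stated desk-scale value are fixed realistic choices documented in the
#' methods vignette.
#'
#' @param seed integer RNG seed.
#' @param nGenes,genomeLength genome layout (two contigs).
#' @param nTrueSnps,fpRate,fractionHeterozygous variant counts/rates.
#' @param violations named integer vector over
#'   `c("lowQD","highFS","lowDP","lowMQ","lowMQRankSum","lowReadPosRankSum",
#'   "lowALTreads","lowHet")`.
#' @param nClusterGroups planted 3-SNP cluster groups.
#' @param nEditingSites planted RNA-only A>G edited sites.
#' @param rnaMeanDepth,wgsMeanDepth mean depths.
#' @param nAbsentNoReads,nAbsentDefaultFiltered,nAbsentCustomFiltered planted
#'   absence-category counts (see [categorizeAbsent()]).
#' @param dbsnpInclusionRate fraction of true SNPs catalogued in dbSNP.
#' @param nGenotypeMismatch planted NS count.
#' @param nWgsOnly planted DS count (WGS-only SNPs in unexpressed genes).
#' @param categoryMix named fractions of nTrueSnps per annotation category.
#' @return A validated [SimulationPlan-class].
#' @examples
#' plan <- simulationPlan(seed = 1, nTrueSnps = 100)
#' @export
simulationPlan <- function(seed = 1L,
                           nGenes = 80L,
                           genomeLength = 600000L,
                           nTrueSnps = 1000L,
                           fpRate = 0.05,
                           fractionHeterozygous = 0.064,
                           violations = c(lowQD = 5L, highFS = 5L, lowDP = 5L,
                                          lowMQ = 5L, lowMQRankSum = 5L,
                                          lowReadPosRankSum = 5L,
                                          lowALTreads = 5L, lowHet = 5L),
                           nClusterGroups = 2L,
                           nEditingSites = 25L,
                           rnaMeanDepth = 40L,
                           wgsMeanDepth = 20L,
                           nAbsentNoReads = 12L,
                           nAbsentDefaultFiltered = 9L,
                           nAbsentCustomFiltered = 56L,
                           dbsnpInclusionRate = 0.9,
                           nGenotypeMismatch = 10L,
                           nWgsOnly = 50L,
                           categoryMix = c(intergenic = 0.57,
                                           upstream_downstream = 0.04,
                                           intronic = 0.205,
                                           exonic = 0.13,
                                           splicing = 0.003,
                                           UTR3_UTR5 = 0.047,
                                           ncRNA = 0.005)) {
  viol <- c(lowQD = 0L, highFS = 0L, lowDP = 0L, lowMQ = 0L,
            lowMQRankSum = 0L, lowReadPosRankSum = 0L,
            lowALTreads = 0L, lowHet = 0L)
  viol[names(violations)] <- as.integer(violations)
  new("SimulationPlan", seed = as.integer(seed), nGenes = as.integer(nGenes),
      genomeLength = as.integer(genomeLength),
      nTrueSnps = as.integer(nTrueSnps), fpRate = fpRate,
      fractionHeterozygous = fractionHeterozygous, violations = viol,
      nClusterGroups = as.integer(nClusterGroups),
      nEditingSites = as.integer(nEditingSites),
      rnaMeanDepth = as.integer(rnaMeanDepth),
      wgsMeanDepth = as.integer(wgsMeanDepth),
      nAbsentNoReads = as.integer(nAbsentNoReads),
      nAbsentDefaultFiltered = as.integer(nAbsentDefaultFiltered),
      nAbsentCustomFiltered = as.integer(nAbsentCustomFiltered),
      dbsnpInclusionRate = dbsnpInclusionRate,
      nGenotypeMismatch = as.integer(nGenotypeMismatch),
      nWgsOnly = as.integer(nWgsOnly),
      categoryMix = categoryMix / sum(categoryMix))
}
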