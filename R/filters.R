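# The hard-filter + custom-filter cascade.
#
# Site filters follow the GATK convention that a missing annotation skips the
# criterion rather than failing it (the rank-sum annotations are absent at
# homozygous sites by construction, so failing on absence would discard nearly
# every homozygous call). Cluster detection runs on the full input set before
# site filters, mirroring GATK VariantFiltration, and removal is applied
# jointly.

#' Alternate-allele ratio
#'
#' `het = aa / t`: reads supporting the alternate allele divided by total
#' reads at the site. The custom filter removes sites with ratio <= 0.10.
#'
#' @param alt_depth reads supporting the alternate allele (aa).
#' @param total_depth total reads at the site (t), must be > 0.
#' @return numeric ratio in `[0, 1]`, vectorised.
#' @examples
#' hetRatio(30, 30)   # 1.0
#' hetRatio(1, 10)    # 0.10 -- fails the aa/t <= 0.10 criterion
#' hetRatio(5, 40)    # 0.125 -- passes
#' @export
hetRatio <- function(alt_depth, total_depth) {
  if (length(alt_depth) != length(total_depth))
    stop("alt_depth and total_depth must have equal length")
  if (any(is.na(alt_depth)) || any(is.na(total_depth)))
    stop("depths must not be NA")
  if (any(alt_depth < 0) || any(total_depth < 0))
    stop("depths must be >= 0")
  if (any(total_depth == 0))
    stop("het ratio is undefined at total_depth = 0")
  if (any(alt_depth > total_depth))
    stop("alt_depth must be <= total_depth")
  alt_depth / total_depth
}

# NA-safe internal ratio: NA when depth evidence is unusable
.hetRatioSafe <- function(alt_depth, total_depth) {
  ifelse(!is.na(alt_depth) & !is.na(total_depth) & total_depth > 0,
         alt_depth / total_depth, NA_real_)
}

.filterMatrix <- function(df, criteria) {
  dpval <- ifelse(!is.na(df$DP), df$DP, as.numeric(df$total_depth))
  het <- .hetRatioSafe(df$alt_depth, df$total_depth)
  naF <- function(x) !is.na(x) & x
  cbind(lowQD = naF(df$QD < criteria@qd_min),
        highFS = naF(df$FS > criteria@fs_max),
        lowDP = naF(dpval < criteria@dp_min),
        lowMQ = naF(df$MQ < criteria@mq_min),
        lowMQRankSum = naF(df$MQRankSum < criteria@mqranksum_min),
        lowReadPosRankSum = naF(df$ReadPosRankSum <
                                  criteria@readpos_ranksum_min),
        lowALTreads = naF(df$alt_depth < criteria@alt_reads_min),
        lowHet = naF(het <= criteria@het_ratio_min))
}

.recordsOf <- function(x) {
  if (is(x, "ConsensusSet") || is(x, "CallSet")) return(variantRecords(x))
  if (!is.data.frame(x))
    stop("expected a ConsensusSet, CallSet or records data.frame")
  if (all(RECORD_COLS %in% names(x))) x else asRecords(x)
}

#' Apply the site-level filters
#'
#' Evaluates every site-level criterion of the cascade (all of
#' [filterCriteria()] except SnpCluster) against each record's representative
#' metrics. A criterion whose annotation metric is absent is skipped, never
#' failed. The depth criterion uses the DP metric when present, else the
#' record's total read depth.
#'
#' @param x a [ConsensusSet-class], [CallSet-class] or records data.frame.
#' @param criteria a [FilterCriteria-class].
#' @return data.frame with key, het_ratio, one logical column per site filter,
#'   and a list-column `failed` of failed filter names.
#' @examples
#' cs <- callSet(data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "G",
#'                          total_depth = 50, alt_depth = 25, QD = 4.9),
#'               "x")
#' applySiteFilters(cs, filterCriteria())$failed
#' @export
applySiteFilters <- function(x, criteria = filterCriteria()) {
  validObject(criteria)
  df <- .recordsOf(x)
  m <- .filterMatrix(df, criteria)
  out <- data.frame(key = recordKeys(df),
                    het_ratio = .hetRatioSafe(df$alt_depth, df$total_depth),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(m))
  out$failed <- lapply(seq_len(nrow(df)), function(i) SITE_FILTERS[m[i, ]])
  rownames(out) <- NULL
  out
}

#' Flag SNP clusters
#'
#' A variant is flagged when it belongs to some set of at least
#' `cluster_size` SNPs on one chromosome whose positions span fewer than
#' `cluster_window_bp` bases (max pos - min pos < window); all members of a
#' qualifying window are flagged. Equivalent to GATK VariantFiltration with
#' clusterSize 3 / clusterWindowSize 35 at the defaults.
#'
#' @param x a [ConsensusSet-class], [CallSet-class] or records data.frame,
#'   sorted by (chrom, pos).
#' @param criteria a [FilterCriteria-class].
#' @return character vector of flagged variant keys.
#' @examples
#' df <- data.frame(chrom = "chr1", pos = c(100, 120, 134),
#'                  ref = "A", alt = "G")
#' flagSnpClusters(df, filterCriteria())  # span 34 < 35: all three flagged
#' @export
flagSnpClusters <- function(x, criteria = filterCriteria()) {
  validObject(criteria)
  df <- .recordsOf(x)
  if (!nrow(df)) return(character())
  by_chrom <- split(seq_len(nrow(df)), df$chrom)
  cs <- criteria@cluster_size
  win <- criteria@cluster_window_bp
  flagged <- logical(nrow(df))
  for (idx in by_chrom) {
    p <- df$pos[idx]
    if (is.unsorted(p)) stop("records must be sorted by (chrom, pos)")
    n <- length(p)
    if (n < cs) next
    # window starting at record j covers j..j+cs-1; if its span < win, all
    # records within [p[j], p[j] + win - 1] are in a qualifying set
    for (j in seq_len(n - cs + 1L)) {
      if (p[j + cs - 1L] - p[j] < win) {
        k <- j + cs - 1L
        while (k < n && p[k + 1L] - p[j] < win) k <- k + 1L
        flagged[idx[j:k]] <- TRUE
      }
    }
  }
  recordKeys(df)[flagged]
}

#' Run the full filter cascade
#'
#' Applies the site-level filters and the SNP-cluster rule jointly: cluster
#' membership is evaluated on the complete input set (all consensus SNPs count
#' toward clusters), then combined with the per-record site verdicts. A record
#' passes iff it fails nothing.
#'
#' @param x a [ConsensusSet-class] (or [CallSet-class] / records data.frame)
#'   sorted by (chrom, pos).
#' @param criteria a [FilterCriteria-class].
#' @return list with elements `passing` (input container subset to the passing
#'   records) and `verdicts` (data.frame: key, het_ratio, per-filter logical
#'   columns including SnpCluster, list-column `failed`, logical `pass`).
#' @examples
#' cs <- callSet(data.frame(chrom = "chr1", pos = c(100, 200),
#'                          ref = "A", alt = "G", genotype = "1/1",
#'                          total_depth = c(30, 9), alt_depth = c(30, 9)),
#'               "x")
#' res <- filterCascade(cs)
#' res$verdicts$failed
#' @export
filterCascade <- function(x, criteria = filterCriteria()) {
  validObject(criteria)
  df <- .recordsOf(x)
  verdicts <- applySiteFilters(df, criteria)
  cluster_keys <- flagSnpClusters(df, criteria)
  verdicts$SnpCluster <- verdicts$key %in% cluster_keys
  verdicts$failed <- lapply(seq_len(nrow(verdicts)), function(i)
    c(verdicts$failed[[i]], if (verdicts$SnpCluster[i]) "SnpCluster"))
  verdicts$pass <- lengths(verdicts$failed) == 0L
  pass_keys <- verdicts$key[verdicts$pass]
  passing <- if (is(x, "ConsensusSet")) {
    subsetByKeys(x, pass_keys)
  } else if (is(x, "CallSet")) {
    callSet(df[recordKeys(df) %in% pass_keys, , drop = FALSE],
            sourceLabel(x), x@contigs)
  } else {
    df[recordKeys(df) %in% pass_keys, , drop = FALSE]
  }
  list(passing = passing, verdicts = verdicts)
}

#' Long-format audit table of filter verdicts
#'
#' @param verdicts the verdicts data.frame from [filterCascade()].
#' @return data.frame with one row per (variant, failed filter); passing
#'   variants contribute one row with filter "PASS".
#' @export
verdictTable <- function(verdicts) {
  rows <- lapply(seq_len(nrow(verdicts)), function(i) {
    f <- verdicts$failed[[i]]
    if (!length(f)) f <- "PASS"
    data.frame(key = verdicts$key[i], filter = f, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(key = character(), filter = character())
  rownames(out) <- NULL
  out
}
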