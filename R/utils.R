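# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# the nine filter names emitted by the cascade
SITE_FILTERS <- c("lowQD", "highFS", "lowDP", "lowMQ", "lowMQRankSum",
                  "lowReadPosRankSum", "lowALTreads", "lowHet")
ALL_FILTERS <- c(SITE_FILTERS, "SnpCluster")

METRIC_COLS <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "DP")

# the 12 single-base substitution classes, ref>alt
SUB_CLASSES <- {
  x <- expand.grid(alt = BASES, ref = BASES, stringsAsFactors = FALSE)
  x <- x[x$ref != x$alt, ]
  sort(paste0(x$ref, ">", x$alt))
}

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

ANNOTATION_CATEGORIES <- c("intergenic", "upstream_downstream", "intronic",
                           "exonic", "splicing", "UTR3_UTR5", "ncRNA")
CODING_EFFECTS <- c("synonymous", "non_synonymous", "stop_gain_loss")

`%||%` <- function(a, b) if (is.null(a)) b else a

variantKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

positionKey <- function(chrom, pos) paste(chrom, pos, sep = ":")

# chrom:pos:ref:alt -> data.frame of parts
splitKey <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 4L
  if (any(bad)) {
    stop("malformed variant key: ", key[bad][1L])
  }
  m <- do.call(rbind, parts)
  data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]),
             ref = m[, 3L], alt = m[, 4L], stringsAsFactors = FALSE)
}

# unphased genotype normalisation: "1|0" and "1/0" both become "0/1"
normalizeGenotype <- function(gt) {
  out <- rep(NA_character_, length(gt))
  ok <- !is.na(gt) & nzchar(gt) & gt != "."
  if (!any(ok)) return(out)
  parts <- strsplit(gsub("|", "/", gt[ok], fixed = TRUE), "/", fixed = TRUE)
  out[ok] <- vapply(parts, function(p) paste(sort(p), collapse = "/"), "")
  out
}

isSnpVec <- function(ref, alt) {
  !is.na(ref) & !is.na(alt) & ref %in% BASES & alt %in% BASES & ref != alt
}

# canonical column set of a records data.frame
RECORD_COLS <- c("chrom", "pos", "ref", "alt", "genotype",
                 "total_depth", "alt_depth",
                 "QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "DP",
                 "is_snp", "filter")

emptyRecords <- function() {
  data.frame(chrom = character(), pos = integer(),
             ref = character(), alt = character(),
             genotype = character(),
             total_depth = integer(), alt_depth = integer(),
             QD = numeric(), FS = numeric(), MQ = numeric(),
             MQRankSum = numeric(), ReadPosRankSum = numeric(),
             DP = numeric(), is_snp = logical(), filter = character(),
             stringsAsFactors = FALSE)
}

# order records by contig (header order when known), then pos, ref, alt
sortRecords <- function(df, contigs = character()) {
  if (nrow(df) == 0L) return(df)
  lev <- unique(c(contigs, sort(unique(df$chrom))))
  o <- order(match(df$chrom, lev), df$pos, df$ref, df$alt)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# coerce a partial data.frame into the canonical records layout
asRecords <- function(df, contigs = character()) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("records need columns: ", paste(miss, collapse = ", "))
  out <- emptyRecords()
  n <- nrow(df)
  if (n == 0L) return(out)
  out <- data.frame(
    chrom = as.character(df$chrom),
    pos = as.integer(df$pos),
    ref = as.character(df$ref),
    alt = as.character(df$alt),
    genotype = if ("genotype" %in% names(df)) as.character(df$genotype) else NA_character_,
    total_depth = if ("total_depth" %in% names(df)) as.integer(df$total_depth) else NA_integer_,
    alt_depth = if ("alt_depth" %in% names(df)) as.integer(df$alt_depth) else NA_integer_,
    QD = if ("QD" %in% names(df)) as.numeric(df$QD) else NA_real_,
    FS = if ("FS" %in% names(df)) as.numeric(df$FS) else NA_real_,
    MQ = if ("MQ" %in% names(df)) as.numeric(df$MQ) else NA_real_,
    MQRankSum = if ("MQRankSum" %in% names(df)) as.numeric(df$MQRankSum) else NA_real_,
    ReadPosRankSum = if ("ReadPosRankSum" %in% names(df)) as.numeric(df$ReadPosRankSum) else NA_real_,
    DP = if ("DP" %in% names(df)) as.numeric(df$DP) else NA_real_,
    is_snp = isSnpVec(as.character(df$ref), as.character(df$alt)),
    filter = if ("filter" %in% names(df)) as.character(df$filter) else NA_character_,
    stringsAsFactors = FALSE
  )
  sortRecords(out, contigs)
}

recordKeys <- function(df) variantKey(df$chrom, df$pos, df$ref, df$alt)

# exclusive membership-pattern counts over named sets of keys.
# Returns one row per non-empty subset of set labels; counts sum to |union|.
patternCounts <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  labels <- names(sets)
  sets <- lapply(sets, function(k) unique(as.character(k)))
  all_keys <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) all_keys %in% s,
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, labels))
  if (length(all_keys) == 0L) member <- matrix(logical(0), ncol = length(sets),
                                               dimnames = list(NULL, labels))
  n <- length(labels)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  names(combos) <- labels
  pattern_id <- function(m) apply(m, 1L, function(r) paste(labels[as.logical(r)],
                                                           collapse = "&"))
  subset_lab <- pattern_id(combos)
  counts <- integer(nrow(combos))
  if (nrow(member)) {
    obs <- pattern_id(member)
    tab <- table(obs)
    counts <- as.integer(tab[subset_lab])
    counts[is.na(counts)] <- 0L
  }
  out <- data.frame(subset = subset_lab,
                    n_sets = rowSums(combos),
                    count = counts,
                    stringsAsFactors = FALSE)
  out[order(out$n_sets, out$subset), , drop = FALSE]
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

fmtNum <- function(x) {
  # compact, locale-independent number formatting for VCF/TSV emission
  ifelse(is.na(x), ".",
         sub("\\.?0+$", "", formatC(x, format = "f", digits = 4)))
}
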