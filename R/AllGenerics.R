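# Generics, accessors and show methods.

#' Variant records of a container
#' @param x a CallSet or ConsensusSet.
#' @return the records data.frame (see [CallSet-class]).
#' @export
setGeneric("variantRecords", function(x) standardGeneric("variantRecords"))

#' @rdname variantRecords
#' @export
setMethod("variantRecords", "CallSet", function(x) x@records)

#' @rdname variantRecords
#' @export
setMethod("variantRecords", "ConsensusSet", function(x) x@records)

#' Number of variant records
#' @param x a CallSet or ConsensusSet.
#' @return integer count of records.
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname nVariants
#' @export
setMethod("nVariants", "CallSet", function(x) nrow(x@records))

#' @rdname nVariants
#' @export
setMethod("nVariants", "ConsensusSet", function(x) nrow(x@records))

#' Variant keys ("chrom:pos:ref:alt") of a container
#' @param x a CallSet or ConsensusSet.
#' @return character vector of keys, in record order.
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname variantKeys
#' @export
setMethod("variantKeys", "CallSet", function(x) recordKeys(x@records))

#' @rdname variantKeys
#' @export
setMethod("variantKeys", "ConsensusSet", function(x) recordKeys(x@records))

#' Source label(s) of a container
#' @param x a CallSet or ConsensusSet.
#' @return for a CallSet its single source label; for a ConsensusSet the
#'   labels of all input call sets.
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))

#' @rdname sourceLabel
#' @export
setMethod("sourceLabel", "CallSet", function(x) x@source)

#' @rdname sourceLabel
#' @export
setMethod("sourceLabel", "ConsensusSet", function(x) x@sourcesAll)

#' Subset a consensus set by variant keys
#'
#' @param x a ConsensusSet.
#' @param keys keys to keep (order of the set is preserved).
#' @return a ConsensusSet restricted to `keys`.
#' @export
subsetByKeys <- function(x, keys) {
  stopifnot(is(x, "ConsensusSet"))
  df <- x@records[recordKeys(x@records) %in% keys, , drop = FALSE]
  rownames(df) <- NULL
  new("ConsensusSet", records = df, sourcesAll = x@sourcesAll,
      minSupport = x@minSupport)
}

setMethod("show", "CallSet", function(object) {
  df <- object@records
  cat("CallSet '", object@source, "': ", nrow(df), " records (",
      sum(df$is_snp), " SNPs) on ", length(unique(df$chrom)),
      " contig(s)\n", sep = "")
  if (nrow(df)) {
    utils::head(df[, c("chrom", "pos", "ref", "alt", "genotype",
                       "total_depth", "alt_depth")], 4L) |> print()
    if (nrow(df) > 4L) cat("...\n")
  }
})

setMethod("show", "ConsensusSet", function(object) {
  df <- object@records
  cat("ConsensusSet: ", nrow(df), " consensus variants from ",
      length(object@sourcesAll), " call sets (",
      paste(object@sourcesAll, collapse = ", "), "), min support ",
      object@minSupport, "\n", sep = "")
  if (nrow(df)) {
    cat("  support: ", paste(sprintf("%d x%d", as.integer(names(table(df$support))),
                                     as.integer(table(df$support))),
                             collapse = ", "),
        "; genotype-concordant: ", sum(df$concordant), "\n", sep = "")
  }
})

setMethod("show", "FilterCriteria", function(object) {
  cat("FilterCriteria:\n",
      "  lowQD: QD < ", object@qd_min,
      " | highFS: FS > ", object@fs_max,
      " | lowDP: depth < ", object@dp_min,
      " | lowMQ: MQ < ", object@mq_min, "\n",
      "  lowMQRankSum: < ", object@mqranksum_min,
      " | lowReadPosRankSum: < ", object@readpos_ranksum_min, "\n",
      "  SnpCluster: >= ", object@cluster_size, " SNPs in ",
      object@cluster_window_bp, " bp\n",
      "  lowALTreads: alt reads < ", object@alt_reads_min,
      " | lowHet: aa/t <= ", object@het_ratio_min, "\n", sep = "")
})

setMethod("show", "DepthTrack", function(object) {
  cat("DepthTrack: ", length(object@depths), " positions, default depth ",
      object@default_depth, "\n", sep = "")
})

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel: ", length(object@genes), " genes, ",
      nrow(object@transcripts), " transcripts (",
      sum(object@transcripts$coding), " coding), ",
      length(object@exons), " exons, ", length(object@cds), " CDS segments\n",
      sep = "")
})

setMethod("show", "SpectrumSummary", function(object) {
  cat("SpectrumSummary (", if (object@collapsed) 6L else 12L, " classes, ",
      sum(object@counts), " SNPs)\n", sep = "")
  print(object@counts)
  cat("transitions ", object@transitions, ", transversions ",
      object@transversions, ", ts/tv ",
      format(object@tstv, digits = 4), "\n", sep = "")
})

setMethod("show", "VerificationResult", function(object) {
  ct <- object@counts
  st <- object@stats
  cat("VerificationResult: ", ct[["verified"]], " verified + ",
      ct[["novel"]], " novel\n", sep = "")
  cat(sprintf("  TS %d, NS %d, DS %d\n", ct[["TS"]], ct[["NS"]], ct[["DS"]]))
  cat(sprintf("  precision %.4f, sensitivity %.4f, specificity %.4f\n",
              st[["precision"]], st[["sensitivity"]], st[["specificity"]]))
})

setMethod("show", "SimulationPlan", function(object) {
  cat("SimulationPlan: seed ", object@seed, ", ", object@nGenes, " genes / ",
      object@genomeLength, " bp, ", object@nTrueSnps, " true SNPs, ",
      object@nEditingSites, " edited sites, ",
      sum(object@violations), " site-filter violators + ",
      object@nClusterGroups, " cluster groups\n", sep = "")
})
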