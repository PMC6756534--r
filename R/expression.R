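# Gene expression: FPKM tables and expression-stratified specificity.

#' Read gene-abundance tables into an expression table
#'
#' Accepts StringTie-style per-gene abundance TSVs; the gene-identifier
#' column ("Gene ID" / "gene_id" / "GeneID", case-insensitive) and the FPKM
#' column are auto-detected. A gene missing from one file contributes FPKM 0
#' for that source; the mean is the arithmetic mean over all supplied
#' sources.
#'
#' @param paths character vector of file paths (>= 1); names become source
#'   labels (default the file base names).
#' @return data.frame: gene_id, one FPKM column per source, mean_fpkm.
#' @export
readExpression <- function(paths) {
  if (!length(paths)) stop("at least one expression table is required")
  labels <- names(paths) %||% NULL
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- make.unique(sub("\\.[^.]*$", "", basename(paths)))
  tabs <- lapply(seq_along(paths), function(i) {
    p <- paths[i]
    if (!file.exists(p)) stop("cannot read expression table: ", p)
    df <- utils::read.table(p, sep = "\t", header = TRUE,
                            check.names = FALSE, quote = "",
                            stringsAsFactors = FALSE, comment.char = "")
    nm <- tolower(gsub("[ _.]", "", names(df)))
    gcol <- which(nm == "geneid")[1L]
    fcol <- which(nm == "fpkm")[1L]
    if (is.na(gcol) || is.na(fcol))
      stop("no gene-identifier/FPKM columns detectable in ", p)
    v <- tapply(as.numeric(df[[fcol]]), as.character(df[[gcol]]), sum)
    data.frame(gene_id = names(v), fpkm = as.numeric(v),
               stringsAsFactors = FALSE)
  })
  genes <- sort(unique(unlist(lapply(tabs, `[[`, "gene_id"))))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (i in seq_along(tabs)) {
    v <- tabs[[i]]$fpkm[match(genes, tabs[[i]]$gene_id)]
    v[is.na(v)] <- 0
    out[[labels[i]]] <- v
  }
  out$mean_fpkm <- rowMeans(out[, labels, drop = FALSE])
  out
}

.fpkmLookup <- function(expr, gene_id) {
  v <- expr$mean_fpkm[match(gene_id, expr$gene_id)]
  v[is.na(v)] <- 0  # genes absent from the table are unexpressed
  v
}

#' Expression-stratified specificity
#'
#' Recomputes specificity = TS / (TS + DS) restricting both TS and DS to
#' SNPs in genes whose mean FPKM exceeds each threshold. SNPs with no
#' containing gene (intergenic) are excluded, since FPKM is gene-level.
#' Also returns the expression levels of the genes carrying SNPs, for the
#' expression-distribution view.
#'
#' @param verification a [VerificationResult-class].
#' @param gene_map data.frame with columns key and gene_id covering both the
#'   RNA SNPs and the DS keys (e.g. row-bound [annotateVariants()] outputs).
#' @param expr expression table from [readExpression()].
#' @param thresholds numeric FPKM cutoffs (>= 0), e.g. `c(0, 0.1, 1, 10)`.
#' @return list with `strata` (data.frame: threshold, specificity, n_snps --
#'   TS SNPs in genes above the cutoff -- n_ds, n_genes) and `genes`
#'   (data.frame: gene_id, mean_fpkm, n_snps for genes carrying RNA SNPs).
#' @export
specificityByFpkm <- function(verification, gene_map, expr,
                              thresholds = c(0, 0.1, 1, 10)) {
  stopifnot(is(verification, "VerificationResult"))
  if (any(is.na(thresholds)) || any(thresholds < 0))
    stop("thresholds must be >= 0")
  pv <- verification@perVariant
  gm <- gene_map[!is.na(gene_map$gene_id) & nzchar(gene_map$gene_id), ,
                 drop = FALSE]
  gene_of <- stats::setNames(gm$gene_id, gm$key)

  ts_keys <- pv$key[pv$label == "TS"]
  ts_gene <- gene_of[ts_keys]
  ts_keep <- !is.na(ts_gene)
  ts_gene <- ts_gene[ts_keep]
  ds_gene <- gene_of[verification@dsKeys]
  ds_gene <- ds_gene[!is.na(ds_gene)]

  ts_fpkm <- .fpkmLookup(expr, ts_gene)
  ds_fpkm <- .fpkmLookup(expr, ds_gene)

  strata <- do.call(rbind, lapply(thresholds, function(th) {
    # threshold 0 applies no restriction, reproducing the unrestricted
    # specificity; positive thresholds keep genes with mean FPKM > threshold
    keep_ts <- if (th > 0) ts_fpkm > th else rep(TRUE, length(ts_fpkm))
    keep_ds <- if (th > 0) ds_fpkm > th else rep(TRUE, length(ds_fpkm))
    n_ts <- if (th > 0) sum(keep_ts) else sum(pv$label == "TS")
    n_ds <- if (th > 0) sum(keep_ds) else length(verification@dsKeys)
    data.frame(threshold = th,
               specificity = if (n_ts + n_ds > 0) n_ts / (n_ts + n_ds)
                             else NA_real_,
               n_snps = n_ts, n_ds = n_ds,
               n_genes = length(unique(c(ts_gene[keep_ts],
                                         ds_gene[keep_ds]))),
               stringsAsFactors = FALSE)
  }))
  snp_genes <- table(ts_gene)
  genes <- data.frame(gene_id = names(snp_genes),
                      mean_fpkm = .fpkmLookup(expr, names(snp_genes)),
                      n_snps = as.integer(snp_genes),
                      stringsAsFactors = FALSE)
  list(strata = strata, genes = genes[order(genes$gene_id), , drop = FALSE])
}
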