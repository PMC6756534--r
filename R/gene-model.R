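# Gene-model loading and normalisation.
#
# Both GFF3 and GTF dialects are accepted through rtracklayer and normalised
# to one internal model: genes, transcripts, exons, CDS (with phase), UTRs
# and introns. UTRs are always re-derived as exon minus CDS and introns as
# gaps between exons, so the two dialects of the same gene yield identical
# models regardless of which optional features the file spells out.

.emptyGeneModel <- function() {
  g0 <- GenomicRanges::GRanges()
  new("GeneModel", genes = g0,
      transcripts = data.frame(tx_id = character(), gene_id = character(),
                               strand = character(), coding = logical(),
                               stringsAsFactors = FALSE),
      exons = g0, cds = g0, utr = g0, introns = g0)
}

.firstChar <- function(x) {
  # first element of a CharacterList / character column, NA when empty
  if (is(x, "List") || is.list(x)) {
    vapply(as.list(x), function(v) if (length(v)) as.character(v[1L])
           else NA_character_, "")
  } else as.character(x)
}

GENE_TYPES <- c("gene", "ncRNA_gene", "pseudogene")
TX_TYPES <- c("mRNA", "transcript", "ncRNA", "lnc_RNA", "lincRNA",
              "misc_RNA", "snoRNA", "snRNA", "rRNA", "tRNA", "miRNA",
              "pseudogenic_transcript")

#' Load a gene model from GFF3 or GTF
#'
#' Coordinates are 1-based inclusive. GFF3 features are linked through
#' ID/Parent; GTF through gene_id/transcript_id attributes. Transcript rows
#' missing from a GTF are synthesised from their exons. A CDS feature with no
#' resolvable parent transcript is an error naming the feature.
#'
#' @param path GFF3 (.gff/.gff3) or GTF (.gtf) file.
#' @return A [GeneModel-class].
#' @examples
#' \dontrun{model <- loadGeneModel("genes.gff3")}
#' @export
loadGeneModel <- function(path) {
  if (!file.exists(path)) stop("cannot read gene model: no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("failed to parse gene model '",
                                          path, "': ", conditionMessage(e),
                                          call. = FALSE))
  if (length(gr) == 0L) return(.emptyGeneModel())
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  gtf <- "transcript_id" %in% colnames(mc) && !"Parent" %in% colnames(mc)

  if (gtf) {
    feat_gene <- as.character(mc$gene_id)
    feat_tx <- as.character(mc$transcript_id)
    feat_id <- ifelse(type %in% GENE_TYPES, feat_gene,
                      ifelse(type %in% TX_TYPES, feat_tx, NA_character_))
    feat_parent <- ifelse(type %in% TX_TYPES, feat_gene, feat_tx)
  } else {
    feat_id <- .firstChar(mc$ID)
    feat_parent <- .firstChar(mc$Parent)
  }

  is_gene <- type %in% GENE_TYPES
  is_tx <- type %in% TX_TYPES
  is_exon <- type == "exon"
  is_cds <- type == "CDS"

  tx_id <- feat_id[is_tx]
  tx_gene <- feat_parent[is_tx]
  tx_strand <- as.character(BiocGenerics::strand(gr))[is_tx]
  tx_range <- gr[is_tx]

  # GTF without explicit transcript rows: synthesise from exons
  exon_tx <- feat_parent[is_exon]
  missing_tx <- setdiff(stats::na.omit(unique(exon_tx)), tx_id)
  if (length(missing_tx) && gtf) {
    for (t in missing_tx) {
      sel <- is_exon & feat_parent == t
      rng <- range(gr[sel])
      tx_id <- c(tx_id, t)
      tx_gene <- c(tx_gene, feat_gene[sel][1L])
      tx_strand <- c(tx_strand, as.character(BiocGenerics::strand(rng))[1L])
      tx_range <- c(tx_range, rng)
    }
  }
  if (anyDuplicated(tx_id)) stop("duplicated transcript ids in ", path)

  cds_tx <- feat_parent[is_cds]
  orphan <- is.na(cds_tx) | !(cds_tx %in% tx_id)
  if (any(orphan)) {
    i <- which(is_cds)[which(orphan)[1L]]
    stop("CDS feature at ", GenomeInfoDb::seqnames(gr)[i], ":",
         BiocGenerics::start(gr)[i], " has no parent transcript")
  }

  # genes: explicit rows, else synthesised from transcript extents
  if (any(is_gene)) {
    genes <- gr[is_gene]
    S4Vectors::mcols(genes) <- NULL
    genes$gene_id <- feat_id[is_gene]
  } else {
    gid <- unique(tx_gene)
    rngs <- lapply(gid, function(g) range(tx_range[tx_gene == g]))
    genes <- do.call(c, rngs)
    genes$gene_id <- gid
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene ids in ", path)

  exons <- gr[is_exon]
  S4Vectors::mcols(exons) <- NULL
  exons$tx_id <- exon_tx
  exons$gene_id <- tx_gene[match(exon_tx, tx_id)]
  if (any(is.na(exons$tx_id)))
    stop("exon feature with no parent transcript in ", path)

  cds <- gr[is_cds]
  phase <- S4Vectors::mcols(gr)$phase
  ph <- if (is.null(phase)) rep(0L, sum(is_cds)) else
    suppressWarnings(as.integer(phase[is_cds]))
  ph[is.na(ph)] <- 0L
  if (any(!ph %in% 0:2)) stop("CDS phase must be 0, 1 or 2 in ", path)
  S4Vectors::mcols(cds) <- NULL
  cds$tx_id <- cds_tx
  cds$gene_id <- tx_gene[match(cds_tx, tx_id)]
  cds$phase <- ph

  transcripts <- data.frame(tx_id = tx_id, gene_id = tx_gene,
                            strand = tx_strand,
                            coding = tx_id %in% unique(cds$tx_id),
                            stringsAsFactors = FALSE)

  # exons must sit inside their gene interval
  gidx <- match(exons$gene_id, genes$gene_id)
  bad <- BiocGenerics::start(exons) < BiocGenerics::start(genes)[gidx] |
    BiocGenerics::end(exons) > BiocGenerics::end(genes)[gidx]
  if (any(bad, na.rm = TRUE))
    stop("exon outside its gene interval in ", path)

  # derive UTRs (exon minus CDS, per coding transcript) and introns using
  # plain interval arithmetic (orders of magnitude faster than per-transcript
  # GRanges set operations on many-gene models)
  ex_tab <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(exons)),
                       start = BiocGenerics::start(exons),
                       end = BiocGenerics::end(exons),
                       tx_id = exons$tx_id, gene_id = exons$gene_id,
                       stringsAsFactors = FALSE)
  cds_tab <- data.frame(start = BiocGenerics::start(cds),
                        end = BiocGenerics::end(cds), tx_id = cds$tx_id,
                        stringsAsFactors = FALSE)
  subtractIv <- function(s, e, cs, ce) {
    # interval [s, e] minus the union of [cs_i, ce_i]; returns matrix
    out <- NULL
    cur <- s
    o <- order(cs)
    for (i in o) {
      if (ce[i] < cur || cs[i] > e) next
      if (cs[i] > cur) out <- rbind(out, c(cur, cs[i] - 1L))
      cur <- max(cur, ce[i] + 1L)
      if (cur > e) break
    }
    if (cur <= e) out <- rbind(out, c(cur, e))
    out
  }
  utr_rows <- list()
  intron_rows <- list()
  ex_by_tx <- split(seq_len(nrow(ex_tab)), ex_tab$tx_id)
  cds_by_tx <- split(seq_len(nrow(cds_tab)), cds_tab$tx_id)
  for (t in names(ex_by_tx)) {
    ei <- ex_by_tx[[t]]
    es <- ex_tab$start[ei]
    ee <- ex_tab$end[ei]
    o <- order(es)
    es <- es[o]; ee <- ee[o]
    ct <- ex_tab$chrom[ei[1L]]
    gid <- ex_tab$gene_id[ei[1L]]
    if (length(es) > 1L) {
      is_ <- ee[-length(ee)] + 1L
      ie_ <- es[-1L] - 1L
      ok <- ie_ >= is_
      if (any(ok))
        intron_rows[[t]] <- data.frame(chrom = ct, start = is_[ok],
                                       end = ie_[ok], tx_id = t,
                                       gene_id = gid,
                                       stringsAsFactors = FALSE)
    }
    ci <- cds_by_tx[[t]]
    if (!is.null(ci)) {
      cs_ <- cds_tab$start[ci]
      ce_ <- cds_tab$end[ci]
      um <- do.call(rbind, lapply(seq_along(es), function(k)
        subtractIv(es[k], ee[k], cs_, ce_)))
      if (!is.null(um) && nrow(um))
        utr_rows[[t]] <- data.frame(chrom = ct, start = um[, 1L],
                                    end = um[, 2L], tx_id = t,
                                    gene_id = gid, stringsAsFactors = FALSE)
    }
  }
  bindGr <- function(lst) {
    if (!length(lst)) return(GenomicRanges::GRanges())
    d <- do.call(rbind, unname(lst))
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
                           tx_id = d$tx_id, gene_id = d$gene_id)
  }
  new("GeneModel",
      genes = BiocGenerics::sort(genes, ignore.strand = TRUE),
      transcripts = transcripts[order(transcripts$tx_id), , drop = FALSE],
      exons = BiocGenerics::sort(exons, ignore.strand = TRUE),
      cds = BiocGenerics::sort(cds, ignore.strand = TRUE),
      utr = BiocGenerics::sort(bindGr(utr_rows), ignore.strand = TRUE),
      introns = BiocGenerics::sort(bindGr(intron_rows), ignore.strand = TRUE))
}

#' Load a reference genome FASTA
#'
#' @param path FASTA file (plain or gzipped). Sequence names are truncated at
#'   the first whitespace, matching common contig naming.
#' @return A [Biostrings::DNAStringSet].
#' @export
loadReferenceGenome <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: no such file: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

# base(s) at 1-based positions; NA for unknown contigs / out-of-range
refBaseAt <- function(genome, chrom, pos) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  out <- rep(NA_character_, length(pos))
  for (ct in unique(chrom)) {
    sel <- chrom == ct
    if (!ct %in% names(genome)) next
    sq <- genome[[ct]]
    ok <- sel & pos >= 1L & pos <= length(sq)
    if (any(ok))
      out[ok] <- as.character(Biostrings::extractAt(
        sq, IRanges::IRanges(pos[ok], pos[ok])))
  }
  out
}
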