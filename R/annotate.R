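# Functional annotation of SNPs against a gene model.
#
# A deliberately minimal annotator: each SNP gets exactly one category by
# precedence (splicing > coding-exonic > UTR > ncRNA-exonic > intronic >
# upstream/downstream > intergenic), ties across genes broken by the smaller
# gene id. Coding SNPs additionally get a codon-level effect by translating
# the reference and alternate codons on the coding strand, honouring CDS
# phase and strand. No HGVS, no multi-transcript reporting.

.grOf <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, df$pos))
}

# per-query best hit by (gene_id, tx_id) lexicographic order
.pickHits <- function(ov, n_query, gene_ids, tx_ids = NULL) {
  sel_gene <- rep(NA_character_, n_query)
  sel_tx <- rep(NA_character_, n_query)
  sel_sub <- rep(NA_integer_, n_query)
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    key <- paste(gene_ids[s], if (is.null(tx_ids)) "" else tx_ids[s])
    o <- order(q, key)
    first <- !duplicated(q[o])
    qf <- q[o][first]
    sf <- s[o][first]
    sel_gene[qf] <- gene_ids[sf]
    if (!is.null(tx_ids)) sel_tx[qf] <- tx_ids[sf]
    sel_sub[qf] <- sf
  }
  list(gene = sel_gene, tx = sel_tx, subject = sel_sub)
}

# coding-order CDS segment table and spliced coding sequence for one tx
.txCoding <- function(model, genome, tx) {
  cds_t <- model@cds[model@cds$tx_id == tx]
  strand <- model@transcripts$strand[model@transcripts$tx_id == tx]
  o <- order(BiocGenerics::start(cds_t))
  if (strand == "-") o <- rev(o)
  cds_t <- cds_t[o]
  chrom <- as.character(GenomeInfoDb::seqnames(cds_t))[1L]
  segs <- data.frame(start = BiocGenerics::start(cds_t),
                     end = BiocGenerics::end(cds_t),
                     phase = cds_t$phase)
  segs$width <- segs$end - segs$start + 1L
  segs$cum_before <- cumsum(c(0L, segs$width))[seq_len(nrow(segs))]
  seq <- Biostrings::DNAStringSet(lapply(seq_len(nrow(segs)), function(i)
    Biostrings::subseq(genome[[chrom]], segs$start[i], segs$end[i])))
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  list(strand = strand, segs = segs,
       seq = paste(as.character(seq), collapse = ""),
       phase1 = segs$phase[1L])
}

.translateCodon <- function(codon) {
  if (is.na(codon) || nchar(codon) != 3L || grepl("[^ACGT]", codon))
    return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}

.revcompBase <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

# codon-level effect of a SNP inside the CDS of transcript `tx`
.codingEffect <- function(coding, pos, alt) {
  segs <- coding$segs
  hit <- which(pos >= segs$start & pos <= segs$end)
  if (!length(hit)) return(NULL)
  i <- hit[1L]
  within <- if (coding$strand == "-") segs$end[i] - pos + 1L
            else pos - segs$start[i] + 1L
  offset <- segs$cum_before[i] + within
  o <- offset - coding$phase1
  if (o < 1L) return(list(effect = NA_character_, aa_change = NA_character_))
  frame_seq <- substring(coding$seq, coding$phase1 + 1L)
  ci <- (o - 1L) %/% 3L + 1L
  pc <- (o - 1L) %% 3L + 1L
  codon <- substr(frame_seq, (ci - 1L) * 3L + 1L, ci * 3L)
  if (nchar(codon) < 3L)
    return(list(effect = NA_character_, aa_change = NA_character_))
  alt_coding <- if (coding$strand == "-") .revcompBase(alt) else alt
  alt_codon <- codon
  substr(alt_codon, pc, pc) <- alt_coding
  ref_aa <- .translateCodon(codon)
  alt_aa <- .translateCodon(alt_codon)
  if (is.na(ref_aa) || is.na(alt_aa))
    return(list(effect = NA_character_, aa_change = NA_character_))
  effect <- if (ref_aa == alt_aa) "synonymous"
            else if (xor(ref_aa == "*", alt_aa == "*")) "stop_gain_loss"
            else "non_synonymous"
  list(effect = effect, aa_change = paste0(ref_aa, "/", alt_aa))
}

#' Annotate variants against a gene model
#'
#' Assigns each SNP exactly one functional category with precedence
#' splicing > exonic (CDS) > UTR > ncRNA-exonic > intronic >
#' upstream/downstream > intergenic; splicing means within `splice_bp` of an
#' exon-intron boundary on the intron side. SNPs in a CDS get a codon effect
#' (synonymous / non_synonymous / stop_gain_loss, the latter when exactly one
#' of the two codons is a stop) computed on the coding strand under the
#' standard genetic code, honouring CDS phase.
#'
#' When a reference genome is supplied, a variant whose stated reference
#' allele disagrees with the genome base is reported with a warning and
#' skipped (category NA).
#'
#' @param x a [ConsensusSet-class], [CallSet-class] or data.frame with chrom,
#'   pos, ref, alt.
#' @param model a [GeneModel-class].
#' @param genome optional [Biostrings::DNAStringSet] reference (required for
#'   coding effects).
#' @param flank_bp upstream/downstream window around genes (default 1000).
#' @param splice_bp intronic splice-site window (default 2).
#' @return data.frame: key, chrom, pos, ref, alt, category, effect,
#'   aa_change, gene_id, tx_id. The keys of reference-mismatched variants are
#'   in `attr(, "reference_mismatch")`.
#' @export
annotateVariants <- function(x, model, genome = NULL, flank_bp = 1000L,
                             splice_bp = 2L) {
  stopifnot(is(model, "GeneModel"))
  df <- .recordsOf(x)
  n <- nrow(df)
  out <- data.frame(key = recordKeys(df), chrom = df$chrom, pos = df$pos,
                    ref = df$ref, alt = df$alt,
                    category = NA_character_, effect = NA_character_,
                    aa_change = NA_character_, gene_id = NA_character_,
                    tx_id = NA_character_, stringsAsFactors = FALSE)
  attr(out, "reference_mismatch") <- character()
  if (!n) return(out)

  snp <- isSnpVec(df$ref, df$alt)
  usable <- rep(TRUE, n)
  if (!is.null(genome)) {
    gbase <- refBaseAt(genome, df$chrom, df$pos)
    mism <- !is.na(gbase) & snp & gbase != df$ref
    if (any(mism)) {
      warning(sum(mism), " variant(s) disagree with the reference base; ",
              "skipped")
      usable[mism] <- FALSE
      attr(out, "reference_mismatch") <- out$key[mism]
    }
  }
  gr <- .grOf(df)
  unassigned <- usable

  assignLayer <- function(targets, label, gene_ids, tx_ids = NULL) {
    if (!any(unassigned) || length(targets) == 0L) return(NULL)
    idx <- which(unassigned)
    # suppress the benign seqinfo-merge warning for disjoint contig sets
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(gr[idx], targets, ignore.strand = TRUE))
    picked <- .pickHits(ov, length(idx), gene_ids, tx_ids)
    hit <- !is.na(picked$gene)
    if (any(hit)) {
      rows <- idx[hit]
      out$category[rows] <<- label
      out$gene_id[rows] <<- picked$gene[hit]
      if (!is.null(tx_ids)) out$tx_id[rows] <<- picked$tx[hit]
      unassigned[rows] <<- FALSE
    }
    list(rows = idx[hit], subject = picked$subject[hit])
  }

  # splice regions: first/last splice_bp bases of each intron
  introns <- model@introns
  splice <- GenomicRanges::GRanges()
  if (length(introns) && splice_bp > 0L) {
    s <- BiocGenerics::start(introns)
    e <- BiocGenerics::end(introns)
    w <- e - s + 1L
    left <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(introns),
      IRanges::IRanges(s, pmin(e, s + splice_bp - 1L)))
    right <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(introns),
      IRanges::IRanges(pmax(s, e - splice_bp + 1L), e))
    splice <- c(left, right)
    splice$gene_id <- rep(introns$gene_id, 2L)
    splice$tx_id <- rep(introns$tx_id, 2L)
  }
  assignLayer(splice, "splicing", splice$gene_id, splice$tx_id)

  cds_hit <- assignLayer(model@cds, "exonic", model@cds$gene_id,
                         model@cds$tx_id)

  assignLayer(model@utr, "UTR3_UTR5", model@utr$gene_id, model@utr$tx_id)

  nc_tx <- model@transcripts$tx_id[!model@transcripts$coding]
  nc_exons <- model@exons[model@exons$tx_id %in% nc_tx]
  assignLayer(nc_exons, "ncRNA", nc_exons$gene_id, nc_exons$tx_id)

  assignLayer(model@introns, "intronic", model@introns$gene_id,
              model@introns$tx_id)

  if (length(model@genes)) {
    flanked <- GenomicRanges::resize(model@genes,
      BiocGenerics::width(model@genes) + 2L * flank_bp, fix = "center")
    flanked$gene_id <- model@genes$gene_id
    assignLayer(flanked, "upstream_downstream", flanked$gene_id)
  }
  out$category[unassigned] <- "intergenic"

  # codon effects for coding-exonic SNPs
  if (!is.null(cds_hit) && length(cds_hit$rows) && !is.null(genome)) {
    cache <- new.env(parent = emptyenv())
    for (r in cds_hit$rows) {
      if (!snp[r]) next
      tx <- out$tx_id[r]
      if (is.na(tx)) next
      if (!exists(tx, envir = cache))
        assign(tx, .txCoding(model, genome, tx), envir = cache)
      eff <- .codingEffect(get(tx, envir = cache), df$pos[r], df$alt[r])
      if (!is.null(eff)) {
        out$effect[r] <- eff$effect
        out$aa_change[r] <- eff$aa_change
      }
    }
  }
  out
}

#' Per-category annotation summary with VAF statistics
#'
#' One row per annotation category with count, percentage of the total,
#' mean and standard deviation of VAF, homozygous-alternate count
#' (VAF >= 0.99) and its within-category percentage. The coding-effect rows
#' (non_synonymous / synonymous / stop_gain_loss) are sub-counts of exonic,
#' marked by `parent = "exonic"`; main-category counts sum to the number of
#' variants.
#'
#' @param annotations output of [annotateVariants()].
#' @param zygosity output of [classifyZygosity()] for the same variants.
#' @return data.frame: category, parent, n, pct, mean_vaf, sd_vaf, n_hom,
#'   pct_hom.
#' @export
categorySummary <- function(annotations, zygosity) {
  if (!setequal(annotations$key, zygosity$key))
    stop("annotations and zygosity must cover the same variant keys")
  if (!nrow(annotations)) {
    return(data.frame(category = character(), parent = character(),
                      n = integer(), pct = numeric(), mean_vaf = numeric(),
                      sd_vaf = numeric(), n_hom = integer(),
                      pct_hom = numeric(), stringsAsFactors = FALSE))
  }
  m <- merge(annotations[, c("key", "category", "effect")],
             zygosity[, c("key", "vaf", "zygosity")], by = "key")
  total <- nrow(m)
  row_for <- function(sel, label, parent) {
    v <- m$vaf[sel]
    hom <- sum(m$zygosity[sel] == "homozygous_alt")
    data.frame(category = label, parent = parent, n = sum(sel),
               pct = 100 * sum(sel) / total,
               mean_vaf = if (any(sel)) mean(v) else NA_real_,
               sd_vaf = if (sum(sel) > 1L) stats::sd(v) else
                 if (any(sel)) 0 else NA_real_,
               n_hom = hom,
               pct_hom = if (any(sel)) 100 * hom / sum(sel) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(ANNOTATION_CATEGORIES, function(cat)
    row_for(!is.na(m$category) & m$category == cat, cat, NA_character_))
  eff_rows <- lapply(CODING_EFFECTS, function(eff)
    row_for(!is.na(m$effect) & m$effect == eff, eff, "exonic"))
  out <- do.call(rbind, c(rows, eff_rows))
  rownames(out) <- NULL
  out
}
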