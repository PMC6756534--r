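# Synthetic input bundles with planted truth.
#
# The generator lays out a small two-contig genome of identical-shape genes
# (two exons, a 300 bp CDS split 121+179 across an intron so the second
# segment exercises CDS phase 2, UTRs on both ends, strands alternating),
# embeds designed coding sequences, and plants every variant class the
# pipeline distinguishes: clean true SNPs per annotation category, per-filter
# violators whose metrics sit just past one threshold, 3-SNP clusters,
# RNA-only A>G edited sites, genotype mismatches, WGS-only SNPs in
# unexpressed genes, and the three non-editing absence classes. Non-cluster
# positions are kept >= 40 bp apart so no accidental SnpCluster arises and
# every verdict is attributable to its planted cause.

.GENE_SPAN <- 720L
.GENE_SPACING <- 3000L
.GENE_OFFSET <- 2000L
.MIN_GAP <- 40L
.SRC <- c("tophat2", "hisat2", "star")

.comp <- function(x) chartr("ACGT", "TGCA", x)

.stopCodons <- c("TAA", "TAG", "TGA")

# --- position bookkeeping (>= gap apart within a chromosome) ----------------

.newUsed <- function() new.env(parent = emptyenv())

.canPlace <- function(used, chrom, pos, gap = .MIN_GAP) {
  v <- used[[chrom]]
  if (is.null(v)) return(TRUE)
  i <- findInterval(pos, v)
  (i < 1L || pos - v[i] >= gap) &&
    (i >= length(v) || v[i + 1L] - pos >= gap)
}

.place <- function(used, chrom, pos) {
  v <- used[[chrom]]
  if (is.null(v)) v <- integer()
  i <- findInterval(pos, v)
  used[[chrom]] <- append(v, pos, after = i)
  invisible(NULL)
}

# sample n positions from an explicit candidate pool (same chromosome)
.samplePool <- function(pool, n, used, chrom, gap = .MIN_GAP) {
  if (n == 0L) return(integer())
  out <- integer()
  for (p in sample(pool)) {
    if (length(out) == n) break
    if (.canPlace(used, chrom, p, gap)) {
      .place(used, chrom, p)
      out <- c(out, p)
    }
  }
  if (length(out) < n)
    stop("inconsistent plan: could not place ", n,
         " positions in a pool of ", length(pool))
  out
}

# sample n (chrom, pos) rows from interval pools via rejection sampling
.sampleRanges <- function(ranges, n, used, gap = .MIN_GAP) {
  if (n == 0L)
    return(data.frame(chrom = character(), pos = integer()))
  w <- ranges$end - ranges$start + 1L
  keep <- w > 0L
  ranges <- ranges[keep, , drop = FALSE]
  w <- w[keep]
  out_c <- character()
  out_p <- integer()
  tries <- 0L
  max_tries <- 200L * n + 2000L
  while (length(out_p) < n && tries < max_tries) {
    tries <- tries + 1L
    i <- sample.int(nrow(ranges), 1L, prob = w)
    p <- ranges$start[i] + sample.int(w[i], 1L) - 1L
    ct <- ranges$chrom[i]
    if (.canPlace(used, ct, p, gap)) {
      .place(used, ct, p)
      out_c <- c(out_c, ct)
      out_p <- c(out_p, p)
    }
  }
  if (length(out_p) < n)
    stop("inconsistent plan: could not place ", n, " interval positions")
  data.frame(chrom = out_c, pos = out_p, stringsAsFactors = FALSE)
}

# --- gene layout -------------------------------------------------------------

.geneLayout <- function(plan) {
  chrom_len <- plan@genomeLength %/% 2L
  per_chrom <- (chrom_len - 2L * .GENE_OFFSET) %/% .GENE_SPACING + 1L
  if (per_chrom < 1L || 2L * per_chrom < plan@nGenes)
    stop("inconsistent plan: genomeLength too small for ", plan@nGenes,
         " genes")
  i <- seq_len(plan@nGenes)
  chrom <- ifelse(i <= ceiling(plan@nGenes / 2L), "chr1", "chr2")
  within <- ifelse(chrom == "chr1", i, i - ceiling(plan@nGenes / 2L))
  s <- .GENE_OFFSET + (within - 1L) * .GENE_SPACING
  strand <- ifelse(i %% 2L == 1L, "+", "-")
  coding <- i %% 10L != 0L
  g <- data.frame(gene_id = sprintf("G%03d", i), tx_id = sprintf("T%03d", i),
                  chrom = chrom, start = s, end = s + .GENE_SPAN - 1L,
                  strand = strand, coding = coding, stringsAsFactors = FALSE)
  plus <- g$strand == "+" | !g$coding  # nc genes use the plus-shape exons
  g$exon1_s <- g$start
  g$exon1_e <- ifelse(plus, g$start + 220L, g$start + 299L)
  g$exon2_s <- ifelse(plus, g$start + 420L, g$start + 499L)
  g$exon2_e <- g$end
  # first/second coding segment in coding order (minus genes read right-left)
  g$cds1_s <- ifelse(g$strand == "+", g$start + 100L, g$start + 499L)
  g$cds1_e <- ifelse(g$strand == "+", g$start + 220L, g$start + 619L)
  g$cds2_s <- ifelse(g$strand == "+", g$start + 420L, g$start + 121L)
  g$cds2_e <- ifelse(g$strand == "+", g$start + 598L, g$start + 299L)
  g$phase1 <- 0L
  g$phase2 <- 2L  # (3 - 121 %% 3) %% 3
  g[!g$coding, c("cds1_s", "cds1_e", "cds2_s", "cds2_e")] <- NA_integer_
  g$chrom_len <- chrom_len
  g
}

# genomic position <-> coding index map for one coding gene (300 bp CDS)
.codingMap <- function(gene) {
  if (gene$strand == "+") {
    data.frame(gpos = c(gene$cds1_s:gene$cds1_e, gene$cds2_s:gene$cds2_e),
               cidx = 1:300)
  } else {
    data.frame(gpos = c(gene$cds1_e:gene$cds1_s, gene$cds2_e:gene$cds2_s),
               cidx = 1:300)
  }
}

# effect of substituting coding-strand base `alt_coding` at coding index ci
.plannedEffect <- function(cds_seq, ci, alt_coding) {
  codon_i <- (ci - 1L) %/% 3L + 1L
  pc <- (ci - 1L) %% 3L + 1L
  codon <- substr(cds_seq, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
  alt_codon <- codon
  substr(alt_codon, pc, pc) <- alt_coding
  ref_aa <- unname(Biostrings::GENETIC_CODE[codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  list(effect = if (ref_aa == alt_aa) "synonymous"
       else if (xor(ref_aa == "*", alt_aa == "*")) "stop_gain_loss"
       else "non_synonymous",
       aa_change = paste0(ref_aa, "/", alt_aa))
}

# --- metric draws ------------------------------------------------------------

.safeMetrics <- function(n, mean_depth, zygosity) {
  total <- pmax(12L, as.integer(round(stats::rnorm(n, mean_depth,
                                                   mean_depth / 5))))
  vaf <- ifelse(zygosity == "hom", 1, stats::runif(n, 0.35, 0.65))
  alt <- ifelse(zygosity == "hom", total,
                pmin(total - 5L, pmax(5L, as.integer(round(vaf * total)))))
  data.frame(total_depth = total, alt_depth = as.integer(alt),
             QD = round(stats::runif(n, 10, 30), 2),
             FS = round(stats::runif(n, 0, 10), 2),
             MQ = round(stats::runif(n, 50, 60), 2),
             MQRankSum = ifelse(zygosity == "hom", NA_real_,
                                round(stats::runif(n, -2, 2), 2)),
             ReadPosRankSum = ifelse(zygosity == "hom", NA_real_,
                                     round(stats::runif(n, -2, 2), 2)),
             DP = as.integer(total))
}

# overwrite one record's metrics so it fails exactly `filter`
.violate <- function(m, filter) {
  i <- seq_len(nrow(m))
  switch(filter,
    lowQD = { m$QD[i] <- round(stats::runif(nrow(m), 0.5, 4.5), 2) },
    highFS = { m$FS[i] <- round(stats::runif(nrow(m), 65, 120), 2) },
    lowDP = {
      m$total_depth[i] <- 9L; m$alt_depth[i] <- 7L; m$DP[i] <- 9L
    },
    lowMQ = { m$MQ[i] <- round(stats::runif(nrow(m), 10, 35), 2) },
    lowMQRankSum = { m$MQRankSum[i] <- round(stats::runif(nrow(m), -20, -13), 2) },
    lowReadPosRankSum = {
      m$ReadPosRankSum[i] <- round(stats::runif(nrow(m), -12, -8.5), 2)
    },
    lowALTreads = {
      m$total_depth[i] <- 30L; m$alt_depth[i] <- 4L; m$DP[i] <- 30L
    },
    lowHet = {
      m$total_depth[i] <- as.integer(round(stats::runif(nrow(m), 51, 80)))
      m$alt_depth[i] <- 5L
      m$DP[i] <- m$total_depth[i]
    },
    stop("unknown filter: ", filter))
  m
}

# --- GFF3 emitter (deterministic; no date stamps) ---------------------------

.writeGff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    atts <- function(id, parent = NULL)
      paste0("ID=", id, if (!is.null(parent)) paste0(";Parent=", parent))
    row <- function(type, s, e, phase, att)
      paste(g$chrom, "synth", type, s, e, ".", g$strand,
            if (is.na(phase)) "." else phase, att, sep = "\t")
    tx_type <- if (g$coding) "mRNA" else "ncRNA"
    lines <- c(lines,
      row("gene", g$start, g$end, NA, atts(g$gene_id)),
      row(tx_type, g$start, g$end, NA, atts(g$tx_id, g$gene_id)),
      row("exon", g$exon1_s, g$exon1_e, NA,
          atts(paste0(g$tx_id, ".e1"), g$tx_id)),
      row("exon", g$exon2_s, g$exon2_e, NA,
          atts(paste0(g$tx_id, ".e2"), g$tx_id)))
    if (g$coding) {
      # genomic order; the coding-first segment carries phase 0
      seg <- data.frame(s = c(g$cds1_s, g$cds2_s), e = c(g$cds1_e, g$cds2_e),
                        ph = c(g$phase1, g$phase2))
      seg <- seg[order(seg$s), ]
      lines <- c(lines,
        row("CDS", seg$s[1], seg$e[1], seg$ph[1],
            atts(paste0(g$tx_id, ".c1"), g$tx_id)),
        row("CDS", seg$s[2], seg$e[2], seg$ph[2],
            atts(paste0(g$tx_id, ".c2"), g$tx_id)))
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

# --- the generator -----------------------------------------------------------

#' Generate a synthetic input bundle with planted truth
#'
#' Writes a complete, deterministic set of pipeline inputs: reference FASTA,
#' GFF3 gene model, three per-aligner RNA VCFs sharing the true SNPs plus
#' private false positives, raw and filtered WGS VCFs, a dbSNP-style VCF, a
#' WGS depth track, StringTie-style FPKM tables, and machine-readable truth
#' tables (per-variant labels and per-gene expression status). The same plan
#' and seed yield byte-identical bundles.
#'
#' @param plan a [SimulationPlan-class].
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest list: `files` (named paths), `truth`
#'   (the per-variant truth data.frame), `genes`, and `expected` counts
#'   (consensus / passing / verified / novel / TS / NS / DS / absence
#'   categories / zygosity) implied by the plan.
#' @examples
#' \dontrun{m <- generateBundle(simulationPlan(seed = 7), tempdir())}
#' @export
generateBundle <- function(plan, outdir) {
  validObject(plan)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(plan@seed)

  genes <- .geneLayout(plan)
  chrom_len <- genes$chrom_len[1L]
  contigs <- c("chr1", "chr2")
  attr(contigs, "lengths") <- c(chr1 = chrom_len, chr2 = chrom_len)

  # designated unexpressed coding genes host the WGS-only (DS) SNPs
  n_unexpr <- if (plan@nWgsOnly > 0L)
    max(2L, ceiling(plan@nWgsOnly / 6L)) else 0L
  coding_ids <- genes$gene_id[genes$coding]
  if (n_unexpr >= length(coding_ids))
    stop("inconsistent plan: not enough coding genes for nWgsOnly")
  unexpr_ids <- utils::tail(coding_ids, n_unexpr)
  genes$expressed <- !(genes$gene_id %in% unexpr_ids)

  # genome with embedded coding sequences
  sense <- setdiff(names(Biostrings::GENETIC_CODE), .stopCodons)
  chrom_seq <- list(chr1 = sample(BASES, chrom_len, replace = TRUE),
                    chr2 = sample(BASES, chrom_len, replace = TRUE))
  cds_seq <- stats::setNames(vector("list", nrow(genes)), genes$gene_id)
  for (k in which(genes$coding)) {
    g <- genes[k, ]
    codons <- c("ATG", sample(sense, 98L, replace = TRUE),
                sample(.stopCodons, 1L))
    sq <- paste(codons, collapse = "")
    cds_seq[[g$gene_id]] <- sq
    map <- .codingMap(g)
    bases <- strsplit(sq, "")[[1L]]
    if (g$strand == "-") bases <- .comp(bases)
    chrom_seq[[g$chrom]][map$gpos] <- bases
  }

  used <- .newUsed()
  refAt <- function(chrom, pos)
    vapply(seq_along(pos), function(i) chrom_seq[[chrom[i]]][pos[i]], "")

  # ---- category allocation of the clean true SNPs
  mix <- plan@categoryMix
  n_cat <- floor(mix * plan@nTrueSnps)
  n_cat["intergenic"] <- plan@nTrueSnps - sum(n_cat[names(n_cat) !=
                                                      "intergenic"])
  if (!any(!genes$coding) && n_cat["ncRNA"] > 0L) {
    n_cat["intergenic"] <- n_cat["intergenic"] + n_cat["ncRNA"]
    n_cat["ncRNA"] <- 0L
  }

  expr_coding <- genes[genes$coding & genes$expressed, , drop = FALSE]
  if (!nrow(expr_coding)) stop("inconsistent plan: no expressed coding genes")

  # pooled CDS positions (and editing candidates) over expressed coding genes
  cds_pool <- do.call(rbind, lapply(seq_len(nrow(expr_coding)), function(k) {
    g <- expr_coding[k, ]
    map <- .codingMap(g)
    cbind(map, data.frame(gene_id = g$gene_id, chrom = g$chrom,
                          strand = g$strand, stringsAsFactors = FALSE))
  }))
  cds_pool$coding_base <- vapply(seq_len(nrow(cds_pool)), function(i)
    substr(cds_seq[[cds_pool$gene_id[i]]], cds_pool$cidx[i],
           cds_pool$cidx[i]), "")

  drawFromPool <- function(pool, n) {
    if (n == 0L) return(pool[0L, , drop = FALSE])
    picked <- integer()
    for (i in sample.int(nrow(pool))) {
      if (length(picked) == n) break
      if (.canPlace(used, pool$chrom[i], pool$gpos[i])) {
        .place(used, pool$chrom[i], pool$gpos[i])
        picked <- c(picked, i)
      }
    }
    if (length(picked) < n)
      stop("inconsistent plan: could not place ", n, " CDS positions")
    pool[picked, , drop = FALSE]
  }

  # editing candidates: coding-strand A whose A>G change is non-synonymous
  edit_ok <- cds_pool$coding_base == "A"
  edit_ok[edit_ok] <- vapply(which(edit_ok), function(i)
    .plannedEffect(cds_seq[[cds_pool$gene_id[i]]], cds_pool$cidx[i],
                   "G")$effect == "non_synonymous", TRUE)

  rows <- list()
  addRows <- function(df) rows[[length(rows) + 1L]] <<- df

  mkCdsRows <- function(pool_rows, role, alt_coding = NULL) {
    n <- nrow(pool_rows)
    if (!n) return(NULL)
    ref <- refAt(pool_rows$chrom, pool_rows$gpos)
    if (is.null(alt_coding)) {
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
      ac <- ifelse(pool_rows$strand == "-", .comp(alt), alt)
    } else {
      ac <- rep(alt_coding, n)
      alt <- ifelse(pool_rows$strand == "-", .comp(ac), ac)
    }
    eff <- lapply(seq_len(n), function(i)
      .plannedEffect(cds_seq[[pool_rows$gene_id[i]]], pool_rows$cidx[i],
                     ac[i]))
    data.frame(role = role, category = "exonic",
               effect = vapply(eff, `[[`, "", "effect"),
               aa_change = vapply(eff, `[[`, "", "aa_change"),
               gene_id = pool_rows$gene_id, chrom = pool_rows$chrom,
               pos = pool_rows$gpos, ref = unname(ref), alt = unname(alt),
               stringsAsFactors = FALSE)
  }

  # clean exonic + the three planted absence classes + editing
  exonic_clean <- drawFromPool(cds_pool, n_cat[["exonic"]])
  addRows(mkCdsRows(exonic_clean, "clean"))
  addRows(mkCdsRows(drawFromPool(cds_pool, plan@nAbsentNoReads),
                    "absent_no_reads"))
  addRows(mkCdsRows(drawFromPool(cds_pool, plan@nAbsentDefaultFiltered),
                    "absent_default"))
  addRows(mkCdsRows(drawFromPool(cds_pool, plan@nAbsentCustomFiltered),
                    "absent_custom"))
  addRows(mkCdsRows(drawFromPool(cds_pool[edit_ok, , drop = FALSE],
                                 plan@nEditingSites), "editing",
                    alt_coding = "G"))
  # WGS-only SNPs in unexpressed genes
  if (plan@nWgsOnly > 0L) {
    unexpr <- genes[genes$gene_id %in% unexpr_ids, , drop = FALSE]
    pool_u <- do.call(rbind, lapply(seq_len(nrow(unexpr)), function(k) {
      g <- unexpr[k, ]
      map <- .codingMap(g)
      cbind(map, data.frame(gene_id = g$gene_id, chrom = g$chrom,
                            strand = g$strand, stringsAsFactors = FALSE))
    }))
    addRows(mkCdsRows(drawFromPool(pool_u, plan@nWgsOnly), "wgs_only"))
  }

  # per-gene feature pools for the non-exonic categories
  simpleRows <- function(chrom, pos, gene_id, category, role = "clean") {
    if (!length(pos)) return(NULL)
    ref <- refAt(chrom, pos)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
    data.frame(role = role, category = category, effect = NA_character_,
               aa_change = NA_character_, gene_id = gene_id, chrom = chrom,
               pos = pos, ref = unname(ref), alt = unname(alt),
               stringsAsFactors = FALSE)
  }

  drawPerGene <- function(gene_rows, poolFun, n, category) {
    if (n == 0L) return(NULL)
    pool <- do.call(rbind, lapply(seq_len(nrow(gene_rows)), function(k) {
      g <- gene_rows[k, ]
      p <- poolFun(g)
      if (!length(p)) return(NULL)
      data.frame(chrom = g$chrom, pos = p, gene_id = g$gene_id,
                 stringsAsFactors = FALSE)
    }))
    picked <- integer()
    for (i in sample.int(nrow(pool))) {
      if (length(picked) == n) break
      if (.canPlace(used, pool$chrom[i], pool$pos[i])) {
        .place(used, pool$chrom[i], pool$pos[i])
        picked <- c(picked, i)
      }
    }
    if (length(picked) < n)
      stop("inconsistent plan: could not place ", n, " ", category,
           " positions")
    pr <- pool[picked, , drop = FALSE]
    simpleRows(pr$chrom, pr$pos, pr$gene_id, category)
  }

  expr_genes <- genes[genes$expressed, , drop = FALSE]
  intronFor <- function(g) {
    # intron interior, clear of the 2 bp splice windows
    if (g$coding) {
      if (g$strand == "+") (g$start + 225L):(g$start + 415L)
      else (g$start + 304L):(g$start + 494L)
    } else (g$start + 225L):(g$start + 415L)
  }
  spliceFor <- function(g) {
    if (g$coding) {
      if (g$strand == "+") c(g$start + 221L, g$start + 222L,
                             g$start + 418L, g$start + 419L)
      else c(g$start + 300L, g$start + 301L, g$start + 497L, g$start + 498L)
    } else c(g$start + 221L, g$start + 222L, g$start + 418L, g$start + 419L)
  }
  utrFor <- function(g) {
    if (!g$coding) return(integer())
    if (g$strand == "+") c(g$start:(g$start + 99L),
                           (g$start + 599L):(g$start + 719L))
    else c(g$start:(g$start + 120L), (g$start + 620L):(g$start + 719L))
  }
  exonNcFor <- function(g) {
    if (g$coding) return(integer())
    c(g$start:(g$start + 220L), (g$start + 420L):(g$start + 719L))
  }

  addRows(drawPerGene(expr_genes[expr_genes$coding, , drop = FALSE],
                      intronFor, n_cat[["intronic"]], "intronic"))
  addRows(drawPerGene(expr_genes[expr_genes$coding, , drop = FALSE],
                      spliceFor, n_cat[["splicing"]], "splicing"))
  addRows(drawPerGene(expr_genes[expr_genes$coding, , drop = FALSE],
                      utrFor, n_cat[["UTR3_UTR5"]], "UTR3_UTR5"))
  nc_genes <- expr_genes[!expr_genes$coding, , drop = FALSE]
  if (nrow(nc_genes))
    addRows(drawPerGene(nc_genes, exonNcFor, n_cat[["ncRNA"]], "ncRNA"))

  updownFor <- function(g) c((g$start - 1000L):(g$start - 1L),
                             (g$end + 1L):(g$end + 1000L))
  addRows(drawPerGene(genes, updownFor, n_cat[["upstream_downstream"]],
                      "upstream_downstream"))

  # intergenic ranges: > 1000 bp from any gene
  ig <- do.call(rbind, lapply(contigs, function(ct) {
    gs <- genes[genes$chrom == ct, , drop = FALSE]
    gs <- gs[order(gs$start), , drop = FALSE]
    starts <- c(10L, gs$end + 1001L)
    ends <- c(gs$start - 1001L, chrom_len - 10L)
    data.frame(chrom = ct, start = starts, end = ends,
               stringsAsFactors = FALSE)
  }))
  igDraw <- function(n, category, role = "clean") {
    if (n == 0L) return(NULL)
    p <- .sampleRanges(ig, n, used)
    simpleRows(p$chrom, p$pos, NA_character_, category, role)
  }
  addRows(igDraw(n_cat[["intergenic"]], "intergenic"))

  # site-filter violators and cluster groups (extra records, intergenic)
  for (f in SITE_FILTERS) {
    v <- igDraw(plan@violations[[f]], "intergenic", paste0("violator_", f))
    addRows(v)
  }
  if (plan@nClusterGroups > 0L) {
    anchors <- .sampleRanges(ig, plan@nClusterGroups, used, gap = 120L)
    for (k in seq_len(nrow(anchors))) {
      p0 <- anchors$pos[k]
      ct <- anchors$chrom[k]
      pos3 <- c(p0, p0 + 15L, p0 + 30L)
      for (p in pos3[-1L]) .place(used, ct, p)
      addRows(simpleRows(rep(ct, 3L), pos3, NA_character_, "intergenic",
                         "cluster"))
    }
  }
  # per-source private false positives
  n_fp <- round(plan@fpRate * plan@nTrueSnps)
  for (s in .SRC) {
    addRows(igDraw(n_fp, "intergenic", paste0("fp_", s)))
  }

  master <- do.call(rbind, rows)
  rownames(master) <- NULL

  # ---- genotypes, depths, metrics, truth flags
  n_all <- nrow(master)
  master$zygosity <- "hom"
  clean_idx <- which(master$role == "clean")
  n_het <- round(plan@fractionHeterozygous * length(clean_idx))
  het_clean <- sample(clean_idx, n_het)
  master$zygosity[het_clean] <- "het"
  special_het <- master$role %in% c("editing", "absent_no_reads",
                                    "absent_default", "absent_custom")
  master$zygosity[special_het] <- "het"
  cluster_or_viol <- grepl("^violator_|^cluster$", master$role)
  master$zygosity[cluster_or_viol] <- "het"

  met <- .safeMetrics(n_all, plan@rnaMeanDepth, master$zygosity)
  for (f in SITE_FILTERS) {
    sel <- master$role == paste0("violator_", f)
    if (any(sel)) met[sel, ] <- .violate(met[sel, , drop = FALSE], f)
  }
  master <- cbind(master, met)
  master$gt_rna <- ifelse(master$zygosity == "hom", "1/1", "0/1")

  # WGS-side truth
  master$in_wgs_raw <- master$role %in% c("clean", "absent_default",
                                          "absent_custom", "wgs_only")
  master$wgs_default_pass <- master$in_wgs_raw &
    master$role != "absent_default"
  master$gt_wgs <- ifelse(master$in_wgs_raw, master$gt_rna, NA_character_)
  mism <- sample(clean_idx, plan@nGenotypeMismatch)
  master$genotype_mismatch <- FALSE
  master$genotype_mismatch[mism] <- TRUE
  master$gt_wgs[mism] <- ifelse(master$gt_rna[mism] == "1/1", "0/1", "1/1")

  master$in_dbsnp <- FALSE
  master$in_dbsnp[clean_idx] <- stats::runif(length(clean_idx)) <
    plan@dbsnpInclusionRate
  master$in_dbsnp[master$role %in% c("absent_no_reads", "absent_default",
                                     "absent_custom", "wgs_only")] <- TRUE

  master$in_rna <- !grepl("^(fp_|wgs_only)", master$role) |
    grepl("^fp_", master$role)  # fp rows are in one RNA set only
  master$absence_category <- NA_character_
  master$absence_category[master$role == "absent_no_reads"] <- "no_reads_mapped"
  master$absence_category[master$role == "editing"] <- "wgs_homozygous"
  master$absence_category[master$role == "absent_default"] <-
    "wgs_het_default_filtered"
  master$absence_category[master$role == "absent_custom"] <-
    "wgs_het_custom_filtered"
  master$planted_filter <- ifelse(grepl("^violator_", master$role),
                                  sub("^violator_", "", master$role),
                                  ifelse(master$role == "cluster",
                                         "SnpCluster", NA_character_))

  # ---- emit RNA VCFs (shared records + per-source private FPs)
  shared <- master[!grepl("^(fp_|wgs_only)", master$role), , drop = FALSE]
  files <- list()
  rna_paths <- character()
  for (s in .SRC) {
    fp <- master[master$role == paste0("fp_", s), , drop = FALSE]
    df <- rbind(shared, fp)
    rec <- data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref,
                      alt = df$alt, genotype = df$gt_rna,
                      total_depth = df$total_depth, alt_depth = df$alt_depth,
                      QD = df$QD, FS = df$FS, MQ = df$MQ,
                      MQRankSum = df$MQRankSum,
                      ReadPosRankSum = df$ReadPosRankSum, DP = df$DP,
                      stringsAsFactors = FALSE)
    path <- file.path(outdir, paste0("rna_", s, ".vcf"))
    writeSnpVcf(callSet(rec, s, contigs), path)
    rna_paths[s] <- path
  }
  files$rna_vcfs <- rna_paths

  # ---- WGS raw + filtered
  wgs <- master[master$in_wgs_raw, , drop = FALSE]
  wgs_zyg <- ifelse(wgs$gt_wgs == "1/1", "hom", "het")
  wmet <- .safeMetrics(nrow(wgs), plan@wgsMeanDepth, wgs_zyg)
  sel_custom <- wgs$role == "absent_custom"
  if (any(sel_custom))
    wmet[sel_custom, ] <- .violate(wmet[sel_custom, , drop = FALSE], "lowHet")
  wgs_rec <- data.frame(chrom = wgs$chrom, pos = wgs$pos, ref = wgs$ref,
                        alt = wgs$alt, genotype = wgs$gt_wgs,
                        total_depth = wmet$total_depth,
                        alt_depth = wmet$alt_depth, QD = wmet$QD,
                        FS = wmet$FS, MQ = wmet$MQ,
                        MQRankSum = wmet$MQRankSum,
                        ReadPosRankSum = wmet$ReadPosRankSum, DP = wmet$DP,
                        filter = ifelse(wgs$wgs_default_pass, "PASS",
                                        "LowQual"),
                        stringsAsFactors = FALSE)
  files$wgs_raw_vcf <- file.path(outdir, "wgs_raw.vcf")
  writeSnpVcf(callSet(wgs_rec, "wgs_raw", contigs), files$wgs_raw_vcf)
  # filtered = default-passing records surviving the custom cascade
  wgs_pass_default <- callSet(wgs_rec[wgs_rec$filter == "PASS", , drop = FALSE],
                              "wgs", contigs)
  wgs_filtered <- filterCascade(wgs_pass_default)$passing
  files$wgs_filtered_vcf <- file.path(outdir, "wgs_filtered.vcf")
  writeSnpVcf(wgs_filtered, files$wgs_filtered_vcf)

  # ---- dbSNP (sites only)
  db <- master[master$in_dbsnp, , drop = FALSE]
  db_rec <- data.frame(chrom = db$chrom, pos = db$pos, ref = db$ref,
                       alt = db$alt, stringsAsFactors = FALSE)
  files$dbsnp_vcf <- file.path(outdir, "dbsnp.vcf")
  writeSnpVcf(callSet(db_rec, "dbsnp", contigs), files$dbsnp_vcf)

  # ---- WGS depth track over every planted position
  dt <- master[, c("chrom", "pos")]
  dt$depth <- pmax(5L, as.integer(round(stats::rnorm(
    n_all, plan@wgsMeanDepth, plan@wgsMeanDepth / 5))))
  dt$depth[master$role == "absent_no_reads"] <- 0L
  dt <- dt[order(dt$chrom, dt$pos), , drop = FALSE]
  files$depth_track <- file.path(outdir, "wgs_depth.tsv")
  writeTsv(dt, files$depth_track)

  # ---- FPKM tables (StringTie-style)
  base_fpkm <- ifelse(genes$expressed,
                      pmax(0.2, round(stats::rlnorm(nrow(genes), 1.5, 1), 3)),
                      0)
  fpkm_paths <- character()
  for (s in .SRC) {
    jit <- round(base_fpkm * stats::runif(nrow(genes), 0.8, 1.25), 3)
    jit[!genes$expressed] <- 0
    tab <- data.frame("Gene ID" = genes$gene_id,
                      "Gene Name" = genes$gene_id,
                      Reference = genes$chrom, Strand = genes$strand,
                      Start = genes$start, End = genes$end,
                      Coverage = round(jit * 7.5, 2), FPKM = jit,
                      TPM = round(jit * 1.1, 3),
                      check.names = FALSE, stringsAsFactors = FALSE)
    path <- file.path(outdir, paste0("fpkm_", s, ".tsv"))
    writeTsv(tab, path)
    fpkm_paths[s] <- path
  }
  files$fpkm_tables <- fpkm_paths

  # ---- reference FASTA + gene model
  files$fasta <- file.path(outdir, "genome.fa")
  genome <- Biostrings::DNAStringSet(vapply(chrom_seq, paste, "",
                                            collapse = ""))
  names(genome) <- contigs
  Biostrings::writeXStringSet(genome, files$fasta)
  files$gff3 <- file.path(outdir, "genes.gff3")
  .writeGff3(genes, files$gff3)

  # ---- truth tables + manifest
  truth <- master
  truth$key <- variantKey(truth$chrom, truth$pos, truth$ref, truth$alt)
  truth <- truth[order(truth$chrom, truth$pos, truth$ref, truth$alt), ,
                 drop = FALSE]
  files$truth_variants <- file.path(outdir, "truth_variants.tsv")
  writeTsv(truth, files$truth_variants)
  gtab <- genes[, c("gene_id", "tx_id", "chrom", "start", "end", "strand",
                    "coding", "expressed")]
  files$truth_genes <- file.path(outdir, "truth_genes.tsv")
  writeTsv(gtab, files$truth_genes)

  n_true <- sum(master$role == "clean")
  n_absent3 <- sum(master$role %in% c("absent_no_reads", "absent_default",
                                      "absent_custom"))
  n_viol <- sum(grepl("^violator_", master$role)) +
    sum(master$role == "cluster")
  expected <- list(
    consensus = nrow(shared),
    passing = nrow(shared) - n_viol,
    verified = n_true + n_absent3,
    novel = plan@nEditingSites,
    TS = n_true + n_absent3 - plan@nGenotypeMismatch,
    NS = plan@nGenotypeMismatch,
    DS = plan@nWgsOnly,
    absence = c(no_reads_mapped = plan@nAbsentNoReads,
                wgs_homozygous = plan@nEditingSites,
                wgs_het_default_filtered = plan@nAbsentDefaultFiltered,
                wgs_het_custom_filtered = plan@nAbsentCustomFiltered))
  # zygosity among passing records only
  pass_roles <- master$role %in% c("clean", "editing", "absent_no_reads",
                                   "absent_default", "absent_custom")
  expected$homozygous <- sum(master$zygosity == "hom" & pass_roles)
  expected$heterozygous <- sum(master$zygosity == "het" & pass_roles)

  manifest <- list(files = files, expected = expected,
                   seed = plan@seed, sources = .SRC)
  manifest_path <- file.path(outdir, "manifest.json")
  # manifest carries bundle-relative paths so equal seeds give
  # byte-identical bundles wherever they are written
  jsonlite::write_json(
    list(seed = plan@seed, sources = .SRC,
         files = lapply(files, function(f) unname(basename(as.character(f)))),
         expected = expected),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$files$manifest <- manifest_path
  manifest$truth <- truth
  manifest$genes <- gtab
  invisible(manifest)
}
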