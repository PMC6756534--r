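---
title: "Consensus calling, filtering and DNA-based verification of RNA-seq SNPs"
author: "rnasnp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus calling, filtering and DNA-based verification of RNA-seq SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasnp)
```

# The problem and the model

Variant calling from RNA-seq inherits two biases that DNA calling does not:
splice-aware alignment is genuinely harder (aligners disagree near
junctions, and misplaced spliced reads materialise as dense runs of false
SNPs), and only expressed positions are observable at all. `rnasnp`
implements the post-calling computation of a multi-aligner workflow built
around both facts.

**Consensus.** Per-aligner call sets are intersected at allele level: the
matching key is (chromosome, position, reference allele, alternate allele),
and a position carrying different alternate alleles in two call sets is
*not* a match. All aligners are weighted equally — there is no confidence
hierarchy — and by default only SNPs present in every call set survive
(`min_support = length(callsets)`). Genotype disagreement between
supporting call sets does not break a consensus match, but it is recorded
in the `concordant` flag and `intersectCallSets(require_concordant = TRUE)`
can demote such records; the source workflow is silent on this point, so
flagging preserves the information without changing the default behaviour.
One record per consensus variant (by default the one from the first-listed
call set; optionally a conservative per-metric worst-case composite) feeds
the downstream filters.

**The filter cascade.** The site-level criteria and their thresholds are:
quality-by-depth QD < 5, Fisher strand bias FS > 60, depth DP < 10, mapping
quality MQ < 40, MQRankSum < −12.5, ReadPosRankSum < −8, alternate-read
support < 5, and alternate-allele ratio

$$Het_i = aa_i / t_i \le 0.10,$$

where $aa_i$ is the alternate-supporting read depth and $t_i$ the total
depth at position $i$. Two boundary conventions deserve mention. First,
the alternate-allele ratio criterion is *inclusive*: a site at exactly
0.10 fails (the formal criteria table of the source workflow says ≤ even
though its prose says <; we follow the table and the tests pin the
boundary). Second, a missing annotation skips its criterion rather than
failing it — the rank-sum annotations are undefined at homozygous sites by
construction, so failing on absence would discard nearly every
homozygous-alternate call. The SnpCluster rule removes *every* member of
any set of ≥ 3 SNPs spanning fewer than 35 bases on one chromosome,
matching GATK VariantFiltration semantics (clusterSize 3,
clusterWindowSize 35); clusters are detected on the full consensus set
before site filtering, because a cluster of bad calls is evidence against
all of its members regardless of their individual metrics.

**Zygosity.** The variant allele frequency VAF = $aa_i/t_i$ of the
representative record classifies a call homozygous-alternate when
VAF ≥ 0.99 (inclusive) and heterozygous otherwise. In the highly inbred
line that motivated the workflow ~93.6% of filtered calls are
homozygous-alternate; the threshold is configurable
(`classifyZygosity(hom_threshold=)`).

**Verification.** With matched WGS calls and a dbSNP-style catalogue, a
filtered RNA SNP is *verified* when its full key is found in either truth
set (dbSNP matching is positional plus alternate-allele membership; rsIDs
are not used), else *novel*:

$$\mathrm{Precision} = \frac{\mathrm{verified}}{\mathrm{verified} + \mathrm{novel}}.$$

Verified calls split into true-verified (TS — the unphased genotype agrees
with the WGS genotype; a dbSNP-only match counts as TS because dbSNP
carries no genotypes) and non-verified (NS — genotype mismatch); WGS SNPs
validated in dbSNP that the RNA set missed are DNA-verified (DS):

$$\mathrm{Sensitivity} = \frac{TS}{TS + NS}, \qquad
  \mathrm{Specificity} = \frac{TS}{TS + DS}.$$

The sensitivity denominator is TS + NS; the source text prints one
occurrence of an undefined "PS" symbol there, which we read as a typo for
NS, the only defined mismatch class. Because it is ambiguous whether
"verified" historically required genotype equality, the result object
reports both `verified` (allele-level) and `verified_genotype` counts.
The DS universe is restricted to coding WGS SNPs when a gene model is
available (the pipeline annotates the WGS set for this), and can further be
masked to RNA-covered positions.

**Absence categorisation and RDD.** Every exonic RNA SNP absent from the
filtered WGS set receives exactly one explanation, decided in this order:
(1) zero WGS depth at the position (`no_reads_mapped`); (2) no call in the
raw WGS despite coverage (`wgs_homozygous` — the DNA carries only the
reference allele, so the site is a candidate RNA–DNA difference); (3)
called but failed the caller's default filters; (4) called, default-passing
but removed by the custom cascade. Rule order matters only for
pathological inputs (a raw call at a zero-depth position); inputs generated
by a coherent caller make the categories naturally disjoint. Candidates in
class (2) with a non-synonymous codon effect are tabulated with their amino
acid change and VAF, and A>G / T>C substitutions are flagged as consistent
with A-to-I editing read on the transcribed strand. All members of a
flagged cluster are removed (not only its interior), matching the GATK
tool the cascade mirrors.

**Annotation.** A deliberately minimal gene-model annotator stands in for
ANNOVAR/VEP: each SNP gets one category by precedence splicing >
coding-exonic > UTR > ncRNA-exonic > intronic > upstream/downstream >
intergenic, with ties across overlapping genes broken toward the
lexicographically smaller gene id for determinism. Coding SNPs are
translated on the coding strand under the standard genetic code, honouring
CDS phase and strand (reverse-complement on minus); `stop_gain_loss` means
exactly one of the two codons is a stop. The up/downstream window is
1000 bp and the splice window 2 bp intron-side — ANNOVAR's defaults, since
the source workflow does not state its windows — and both are arguments of
`annotateVariants()`. The annotator handles one gene model at a time; the
source study annotated against three databases jointly and does not state
its merge rule, so merging is out of scope.

**Expression stratification.** Mean FPKM per gene (arithmetic mean across
the supplied abundance tables, genes absent from a table contributing 0)
stratifies specificity: at each threshold θ > 0, TS and DS are restricted
to SNPs in genes with mean FPKM > θ. θ = 0 applies no restriction and
reproduces the unrestricted specificity — this convention makes the
published contrast ("specificity rises from ~66% to >82% above
FPKM 0.1") directly computable, with the silent genes that harbour missed
DNA SNPs dropping out only at positive thresholds. Intergenic SNPs are
excluded from stratification because FPKM is gene-level.

# Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `min_support` | all call sets | count | full intersection is the published choice; lower values trade precision for sensitivity |
| QD / FS / DP / MQ / rank-sum cuts | 5 / 60 / 10 / 40 / −12.5 / −8 | caller units | the published hard-filter table |
| `cluster_size` / `cluster_window_bp` | 3 / 35 | SNPs / bp | GATK VariantFiltration settings the workflow cites |
| `alt_reads_min` | 5 | reads | published custom filter |
| `het_ratio_min` | 0.10 (fail when ≤) | ratio | published custom filter, table convention |
| `hom_threshold` | 0.99 (hom when ≥) | VAF | published zygosity boundary |
| `flank_bp` / `splice_bp` | 1000 / 2 | bp | ANNOVAR defaults; unstated in the source |
| FPKM thresholds | 0, 0.1, 1, 10 | FPKM | 0.1 is the published expression cut; the rest span the distribution |

# The synthetic world

`simulationPlan()` states a world and `generateBundle()` writes it
deterministically (same seed ⇒ byte-identical files). The genome is two
contigs of identical-shape genes — two exons, a 300 bp CDS split 121 + 179
across a 199 bp intron so the second segment carries phase 2, UTRs on both
ends, strands alternating, every tenth gene non-coding — with designed
coding sequences embedded in otherwise uniform random DNA. Planted variant
classes: clean true SNPs allocated over annotation categories; per-filter
violators whose metrics sit just past exactly one threshold (e.g. the
alternate-allele-ratio violator has 5 alternate reads in ≥ 51 so *only*
the ratio criterion fires); 3-SNP clusters; RNA-only A>G edited sites
placed where the change is non-synonymous; genotype mismatches (RNA 1/1 vs
WGS 0/1); WGS-only SNPs confined to unexpressed (FPKM-0) genes; and the
three non-editing absence classes. All other positions are kept ≥ 40 bp
apart so no accidental cluster forms and every verdict is attributable.

Where the source study states a quantity, the default is that quantity:
heterozygous fraction 0.064, absence-class counts in the reported
8.7 : 12 : 24.5 : 54.8 proportions (scaled to the default 25 edited
sites), annotation-category mix in the reported proportions
(57% intergenic, 13% exonic, ...). Quantities with no stated desk-scale
value were fixed once at realistic levels: 80 genes over 600 kb, 1000 true
SNPs, 5% per-aligner private false calls, RNA depth 40×, WGS depth 20×,
dbSNP inclusion 0.9.

What the generator deliberately does **not** emulate: read-level error
(there are no FASTQ/BAM, so alignment artefacts beyond the planted
violators do not arise); a transition-enriched substitution spectrum
(non-editing alternate alleles are uniform, so a bundle's ts/tv hovers
near 0.5 rather than the 2–3 of real coding sequence — spectrum tests
therefore establish counting correctness, not mutation biology); linkage,
allele-specific expression, or depth heterogeneity along transcripts. A
green test on a bundle establishes that the bookkeeping, thresholds and
formulas are exact on planted truth; it does not establish performance on
real alignments.

# Numerical and degenerate-input conventions

* All internal coordinates are 1-based; BED depth tracks are converted at
  the I/O boundary.
* Depth provenance: allele depths come from the genotype AD field when
  present; total depth is the AD sum, falling back to FORMAT DP, then
  INFO DP. Records with no usable depth skip the depth-based filters.
* Multi-sample VCFs: only the first sample column is read (the source data
  are single-sample per aligner).
* `hetRatio()` and `classifyZygosity()` error on zero total depth rather
  than returning 0 — a 0 would silently misclassify.
* ts/tv of a transversion-free non-empty set is `Inf` (an explicit flag);
  of an empty set, `NA`. Percent columns of empty categories are `NA`.
* A variant whose stated reference allele disagrees with the genome base
  is warned about and skipped (category `NA`), never silently re-anchored.
* VCF writing uses an internal VCFv4.2 emitter (FILTER column carries the
  semicolon-joined failed-filter names); reading goes through
  VariantAnnotation, so round-trip tests cross two independent codebases.

# Known limitations

* The annotator reports one category and one transcript per SNP; no HGVS,
  no multi-transcript or regulatory-region reporting.
* Verification is key-based; no realignment or rsID mapping.
* Indels are parsed and preserved but excluded from all SNP statistics.
* The pipeline is single-threaded; the intended scale is the desk-scale
  synthetic world and small-to-medium cohorts, not population VCFs.
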