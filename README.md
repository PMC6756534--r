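# rnasnp

Post-calling analysis of SNPs detected from RNA-seq, for researchers who
call variants from transcriptome data in non-model organisms and want to
know how far those calls can be trusted against DNA truth.

Calling SNPs from RNA-seq is attractive — the reads concentrate in the
expressed, functionally interesting fraction of the genome — but the
transcriptome's splice structure makes aligners disagree and inflates false
positives. `rnasnp` implements the post-calling half of a multi-aligner
workflow: it takes per-aligner VCF call sets (e.g. TopHat2-, HiSAT2- and
STAR-aligned reads each followed by GATK HaplotypeCaller), keeps only SNPs
that all aligners agree on, applies a published hard + custom filter
cascade, and then quantifies accuracy against matched whole-genome
sequencing (WGS) and a dbSNP-style catalogue. Sites that the RNA supports
but the DNA provably lacks are reported as candidate RNA–DNA differences
(RDD), the signature of post-transcriptional editing (canonically A-to-I,
read as A>G on the transcribed strand).

## The model

* **Consensus.** SNPs are matched across call sets on the full key
  (chrom, pos, ref, alt); all aligners are weighted equally and only keys
  reaching `min_support` (default: all) survive.
* **Filter cascade** (defaults as published):
  QD < 5, FS > 60, DP < 10, MQ < 40, MQRankSum < −12.5,
  ReadPosRankSum < −8, ≥ 3 SNPs in a 35 bp window (SnpCluster),
  alternate-supporting reads < 5, and alternate-allele ratio
  *Het*ᵢ = *aa*ᵢ/*t*ᵢ ≤ 0.10. Missing annotations skip a criterion
  (GATK convention).
* **Zygosity.** VAF = alt reads / total reads; VAF ≥ 0.99 is
  homozygous-alternate, below that heterozygous.
* **Verification.** A filtered SNP is *verified* if its key is found in the
  WGS calls or dbSNP, else *novel*;
  precision = verified/(verified+novel). Among verified calls, TS
  (true-verified, genotype agrees with the DNA), NS (genotype mismatch) and
  DS (WGS SNPs validated in dbSNP that the RNA missed) give
  sensitivity = TS/(TS+NS) and specificity = TS/(TS+DS).
* **Absence categories.** Each exonic RNA SNP missing from the filtered WGS
  set is explained by exactly one of: no WGS reads at the position / the
  position is homozygous in the DNA (RDD candidate) / lost to the caller's
  default filters / lost to the custom cascade.
* **Expression stratification.** Specificity is recomputed restricting TS
  and DS to genes above each mean-FPKM threshold, reproducing the gain in
  specificity when unexpressed genes are set aside.

A deterministic synthetic-data generator (`simulationPlan()` +
`generateBundle()`) builds complete input bundles — genome FASTA, GFF3 gene
model, three RNA VCFs, raw/filtered WGS VCFs, dbSNP VCF, depth track, FPKM
tables — with machine-readable planted truth for every one of those
quantities, so the whole pipeline is testable without any downloads.

## Worked example

```r
library(rnasnp)

m <- generateBundle(simulationPlan(seed = 7, nTrueSnps = 400), "demo_bundle")
sets <- lapply(names(m$files$rna_vcfs),
               function(s) readSnpVcf(m$files$rna_vcfs[[s]], s))
cons <- intersectCallSets(sets)
cons
#> ConsensusSet: 548 consensus variants from 3 call sets (tophat2, hisat2,
#>   star), min support 3
#>   support: 3 x548; genotype-concordant: 548

fc <- filterCascade(cons)
nVariants(fc$passing)
#> [1] 502

verifyAgainst(fc$passing,
              readSnpVcf(m$files$wgs_filtered_vcf, "wgs"),
              readSnpVcf(m$files$dbsnp_vcf, "dbsnp"))
#> VerificationResult: 477 verified + 25 novel
#>   TS 467, NS 10, DS 50
#>   precision 0.9502, sensitivity 0.9790, specificity 0.9033
```

The 548 consensus SNPs are the 400 planted true SNPs plus 46 planted filter
violators and cluster members (removed by the cascade: 548 − 46 = 502
pass), 25 planted RNA-only edited sites and 77 planted WGS-absence cases.
The 25 novel calls are exactly the edited sites — they are in no DNA truth
set — and the verification counts equal the planted ones: 10 genotype
mismatches (NS) and 50 WGS-only SNPs in unexpressed genes (DS).

`runPipeline()` chains all stages (consensus → filter → classify →
annotate → verify → absence/RDD → FPKM stratification) and writes report
files plus a `summary.json`; `inst/scripts/rnasnp-cli.R` exposes the same
stages as shell subcommands.

## Acceptance script

`scripts/acceptance.R` regenerates a synthetic bundle from the given seed,
runs the complete pipeline on it, and writes the acceptance JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
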