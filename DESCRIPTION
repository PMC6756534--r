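Package: rnasnp
Title: Consensus Calling, Filtering and DNA-Based Verification of SNPs from
    RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-calling analysis of single-nucleotide variants detected from
    RNA-seq. Intersects per-aligner VCF call sets into consensus SNPs, applies
    a GATK-style hard-filter plus custom filter cascade (quality-by-depth,
    strand bias, depth, mapping quality, rank sums, SNP clusters, alternate
    read support and alternate-allele ratio), classifies zygosity from variant
    allele frequency, summarises the substitution spectrum, annotates variants
    against a gene model with codon-level coding effects, verifies calls
    against whole-genome sequencing and dbSNP truth sets (precision,
    sensitivity, specificity), categorises RNA-only sites to flag candidate
    RNA-DNA differences such as A-to-I editing, and stratifies specificity by
    gene expression (FPKM). Includes a deterministic synthetic-data generator
    that plants ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
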