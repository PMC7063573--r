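Package: editscope
Title: Genotyping Somatic CRISPR Edits, Aberrant Splicing, and Expression
    from Aligned RNA-seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing somatic CRISPR-Cas9 editing in bulk and
    single-cell RNA-seq libraries that capture both spliced transcripts and
    genomic amplicons over guide target sites (TARGET-seq-like designs).
    Reads aligned reads (SAM), classifies per-read editing alleles at sgRNA
    cut sites by CIGAR walking (indels, substitutions, and split-read large
    deletions over 10 kb), rolls calls up to per-sample genotypes and cohort
    editing fractions, propagates edits and exon-skipping splice variants
    into the coding sequence to report frameshift and premature-stop
    consequences, quantifies aberrant splice-junction fractions, performs
    masked-exon read counting with splicing-ratio-weighted effective-length
    FPKM, and applies median-absolute-deviation single-cell quality control
    and marker co-expression classification. A deterministic synthetic-data
    generator with a ground-truth manifest makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    scater,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
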