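Package: apecontam
Title: Human Contamination Estimation in Great-Ape Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and quantifies human contamination in short-read
    sequencing data from great-ape samples (blood, tissue, fecal, museum)
    mapped to the human reference genome. Builds panels of clade-diagnostic
    autosomal sites from cohort VCFs (positions where a species complex is
    near-fixed for a non-reference allele and a human cohort is fixed for
    the reference allele), counts filtered reads at those sites from BAM
    alignments or samtools-mpileup text, and reports the contamination
    fraction with a per-chromosome standard deviation and the number of
    positions observed. Includes an in-silico read mixer, downsampling and
    cross-clade validation experiments, and a fully synthetic fixture
    generator (reference FASTA, cohort VCF, masks, aligned reads with
    planted truth) so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
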