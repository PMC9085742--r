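Package: mpravar
Title: Functional Profiling and Prioritization of Rare Noncoding Variants
    with Massively Parallel Reporter Assays
Version: 0.1.0
Authors@R:
    person("MPRA", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for profiling the regulatory consequences
    of rare noncoding single-nucleotide variants with a barcoded massively
    parallel reporter assay (MPRA) and for prioritizing candidate pathogenic
    variants by the overlap between proband phenotype (HPO) terms and the HPO
    terms of transcription factors bound at the variant site. Includes a
    synthetic-data generator with planted ground truth (cohort variants,
    reference sequence, plasmid/cDNA counts under a negative-binomial noise
    model, TF binding intervals, HPO annotations), golden-gate-aware oligo
    library design, FASTQ barcode quantification, median-of-ratios
    normalization with negative-binomial Wald testing of regulatory activity,
    allelic effect z-scores, and hypergeometric phenotype-overlap ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    optparse,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
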