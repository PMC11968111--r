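Package: tssUsage
Title: Transcription Start Site Cluster Prediction, Quantification, and
    Differential Usage Testing for 5' Single-Cell RNA-Seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for analysing transcription start sites (TSSs) from
    5' single-cell RNA-seq data. Supports both paired-end ("on-site") data,
    in which the 5' end of Read 1 marks the genuine TSS, and single-end
    ("near-site") data, in which only Read 2 carries cDNA and clusters must
    be shifted towards the 5' end by a learned, intron-aware adjustment
    distance. Provides distance-based TSS clustering per sample, cross-sample
    merging of clusters into unified non-overlapping intervals, per-cell UMI
    quantification into sparse cluster-by-cell count matrices, and
    differential TSS usage testing between biological conditions with a
    binomial generalized linear mixed model (logit link, per-sample Gaussian
    random intercept) at single-cell or pseudo-bulk level. Includes rank-sum
    and Wasserstein-permutation comparator tests, a simulation framework
    with known null/alternative usage structure for benchmarking type I
    error and power, accuracy metrics against TSS annotations, and a
    deterministic synthetic-data generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, SingleCell, GeneRegulation,
    DifferentialSplicing, Sequencing
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'gene-models.R'
    'clustering.R'
    'quantify.R'
    'glmm.R'
    'du-test.R'
    'evaluate.R'
    'fixtures.R'
    'mapped-tss.R'
    'nearsite.R'
    'pipeline.R'
    'simulate.R'
    'tssUsage-package.R'
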