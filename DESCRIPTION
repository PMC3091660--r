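Package: gcvar
Title: Intra-Genomic GC Content Heterogeneity Analysis for Prokaryotic
    Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the GCVAR statistic, a log-transformed mean absolute
    deviation of non-overlapping window GC fractions from the chromosome
    mean GC content, for prokaryotic chromosome sequences. Provides
    windowed GC profiling with bedGraph track export, Gaussian diagnostics
    of within-chromosome GC residuals, loess trend summaries of GCVAR
    against mean GC, and ordinary least squares models with sum-to-zero
    factor coding relating GCVAR (or mean GC) to phylum, oxygen
    requirement and other lifestyle covariates, including per-phylum GC
    slopes and linear contrasts such as archaea versus bacteria. A
    synthetic-data module simulates chromosomes with optional GC-shifted
    island blocks and cohorts of chromosome records with known regression
    truth, so every pipeline stage is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    e1071
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'diagnostics.R'
    'gc-profile.R'
    'regression.R'
    'sequence-io.R'
    'synthetic-data.R'
    'utils.R'
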