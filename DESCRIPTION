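Package: comotif
Title: Co-Occupancy, Composite Motif and Reporter-Synergy Analysis for
    Transcription Factor ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting combinatorial transcription-factor input at
    cis-regulatory modules from ChIP-seq peak sets: permutation-based peak
    co-occupancy enrichment, position-weight-matrix scanning with a
    fraction-of-maximum threshold, classification of peaks by canonical versus
    divergent Gli-binding motif content, a reverse-complement-collapsed 8-mer
    census with ranking, spacing and orientation grids for Gli-binding-motif /
    E-box composite sites, integration with differential-expression tables and
    marker gene sets, and a super-additivity test for dual-luciferase reporter
    assays. A seeded synthetic-data generator emulates all required inputs so
    the full pipeline runs and is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'comotif-package.R'
    'cooccupancy.R'
    'expression.R'
    'intervals-io.R'
    'motifs.R'
    'pipeline.R'
    'reporter.R'
    'spacing.R'
    'synthetic-data.R'
    'utils.R'
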