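Package: bchromcnv
Title: Read-Depth Copy-Number Analysis of B-Chromosome-Derived Genome
    Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A windowed read-depth pipeline for estimating the copy number
    of B-chromosome-derived genome fragments across individuals and
    populations. Provides a synthetic-cohort simulator (repeat-annotated
    reference, planted per-individual fragment copy numbers with
    population structure, GC-biased short reads), GC-corrected copy-number
    estimation in fixed-size repeat-masked windows calibrated on diploid
    control regions, fragment- and population-level copy-number summaries,
    spacer-joined pseudo-scaffold construction from consensus fragments,
    and flow-cytometry genome-size and sequence-density computations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
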