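Package: taqmap
Title: Gene Mapping from Endonuclease-Induced Genome Rearrangements in Hybrid Yeast
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis toolkit for restriction-endonuclease
    mutagenesis ("TAQing") mapping experiments in hybrid diploid yeast.
    Simulates fusion diploids of two divergent parents with a dense SNV
    marker map, plants double-strand-break-derived rearrangements
    (break-induced repair, short gene conversion, translocation,
    aneuploidy, circularization, deletion) anchored at TCGA recognition
    sites, applies planktonic selection against a three-locus flocculation
    architecture, and emits sequencing-evidence tracks with known truth.
    A caller genotypes markers from allele depths, segments loss of
    heterozygosity, classifies events from reciprocal coverage changes and
    junction reads, and detects aneuploidy and chromosome circularization.
    A comparative stage aggregates windowed homozygosity across mutants,
    tests loss-of-heterozygosity hotspots with a binomial model, tabulates
    aneuploidy frequencies and reports candidate genes. Also includes the
    small-variant filter chain, coding-consequence annotation, tandem
    repeat-unit counting, a serial-passage spontaneous-mutagenesis
    simulator, and the phenotype statistics (flocculation score, Welch's
    t-test, relative expression) used in such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    BiocGenerics,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
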