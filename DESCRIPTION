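Package: aneukit
Title: Characterization of Aneuploid Cancer Genomes from Multi-Library
    Sequencing Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Downstream characterization of highly rearranged, aneuploid
    cancer genomes sequenced with several library technologies.  Provides
    cross-library single-linkage clustering of interchromosomal
    translocation breakpoints, lesser-allele-fraction windows and
    loss-of-heterozygosity (LOH) segmentation, a het/hom-ratio LOH
    simulation, ploidy-normalized read-depth profiles, multi-library
    variant concordance and panel recall, gene-fusion breakpoint support
    checks, and parsing and error-filtering of 384-well linked-compartment
    (LFR) variant annotations.  Ships a synthetic aneuploid-genome
    generator with planted truth so every stage is testable without
    external data, plus published summary tables as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
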