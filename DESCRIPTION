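Package: kappa3C
Title: Viewpoint 3C-seq Interaction Analysis of the Mouse Igkappa Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of chromosome-conformation-capture
    sequencing (3C-seq) viewpoint profiles across the mouse immunoglobulin
    kappa light-chain locus. Builds and filters BglII restriction-fragment
    maps, annotates fragments with Vkappa gene segments, transcription-factor
    binding sites and histone marks by same-fragment colocalization,
    normalizes per-fragment read counts to reads per million, aggregates
    interaction frequencies by locus region and 100-kb bins, and contrasts
    fragment classes with Mann-Whitney rank-sum tests, fold-change
    classification across a pre-BCR signaling gradient, inter-viewpoint and
    usage-category correlations. Includes a 3D DNA-FISH inter-probe distance
    module and a synthetic-data generator that emulates the locus interaction
    structure so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
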