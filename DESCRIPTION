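Package: pactrace
Title: Simulation and Inference of Headful Packaging of Host DNA by Temperate Phages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying lateral-transduction-like packaging of bacterial
    DNA by pac-type temperate phages. Provides a mechanistic simulator of
    att-site integration and pac-initiated processive headful packaging
    (circularly permuted, terminally redundant virion DNA, jittered initiation
    cleavage, geometric packaging series, uniform background host packaging),
    paired-end read generation with per-read truth, a k-mer seed read
    classifier that detects phage/host hybrid att-junction reads, and
    coverage-profile inference of the packaging model: headful size from wave
    periodicity, terminal redundancy, packaging processivity, pac position,
    directionality and host-flank extent, together with the supporting
    proportion and contingency statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
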