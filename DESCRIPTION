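Package: ptrearr
Title: Split-Read Detection and Classification of Plastid Genome Rearrangements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies rearrangement junctions in circular
    quadripartite plastid genomes from paired-end short reads. Provides a
    seeded simulator for synthetic plastomes carrying engineered junctions
    with controlled microhomology or inserted bases, a gap-free local
    alignment engine with decoy sequences guarding the natural inverted
    repeat boundaries, split-read junction calling with the overlap
    (microhomology) statistic, inverted-repeat coordinate folding,
    coverage-normalized rearrangement rates and tracks, direct-repeat
    annotation of junction sequences, and chi-squared comparison of
    microhomology usage between samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
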