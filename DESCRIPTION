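Package: defenscan
Title: Antiphage Defense System Annotation and Phage-Host Linkage for
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-based annotation of antiphage defense systems (RM, BREX,
    DISARM, Abi, Zorya, Thoeris, Shedu, Gabija, Hachiman, CRISPR-Cas) in
    assembled metagenomic contigs, cas-module calling and type/subtype
    classification, de novo CRISPR array detection with spacer extraction and
    array-size statistics, spacer-to-virome matching by seed-and-extend local
    alignment under identity and query-coverage thresholds, and construction
    of the bipartite spacer-virome network. Includes a seeded synthetic
    community generator with a ground-truth manifest for end-to-end recovery
    testing, and report compilation of per-phylum abundance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    igraph,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
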