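Package: plastidkit
Title: Comparative Chloroplast Genome Analysis and Divergence Hotspot Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of circular chloroplast (plastid)
    genomes: detection and canonicalization of the quadripartite LSC/IRa/SSC/IRb
    structure with inverted-repeat junction gene analysis, perfect microsatellite
    (SSR) scanning with MISA-style unit thresholds, maximal large-repeat detection
    at bounded Hamming distance (forward, reverse, complement and palindromic
    types), alignment divergence statistics (variable and parsimony-informative
    sites, nucleotide diversity, p-distance), sliding-window identification of
    divergence hotspots by a mean plus two standard deviations rule, a
    desk-scale neighbor-joining and parsimony phylogeny stage, and a seeded
    synthetic-plastome simulator that plants known structures so that every
    stage can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
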