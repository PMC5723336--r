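Package: placeprof
Title: Gene-Centric Quantification of Marker Genes by Phylogenetic Read Placement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recruits short metagenomic reads to protein-coding marker genes by
    translated local alignment, places them on curated reference phylogenies
    with an evolutionary-placement (per-edge maximum likelihood) algorithm
    under amino-acid substitution models with discrete-gamma rate
    heterogeneity, excludes outgroup placements, and converts placed-read
    counts into percent-of-prokaryotic-community estimates by length-normalized
    comparison to the single-copy core gene rpoB. Includes a synthetic
    community and read simulator with known ground truth for end-to-end
    validation, with benchmark scenarios for nitrogen-cycle marker genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools,
    withr,
    optparse
Config/testthat/edition: 3
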