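Package: ecoassembly
Title: Null-Model Estimation and Mapping of Microbial Community Assembly
    Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the relative influences of ecological assembly
    processes (homogeneous selection, variable selection, dispersal
    limitation, homogenizing dispersal, and an undominated remainder) on
    microbial community turnover using phylogenetic and taxonomic null
    models. Computes abundance-weighted beta mean nearest taxon distance
    (bMNTD) and its tip-shuffle standardized score (bNTI), the
    abundance-based Raup-Crick metric built on Bray-Curtis dissimilarity
    (RC-bray), per-community process-influence fractions, a
    diversification-plus-assembly simulator for validating the inference
    rules, and a spatial stage (Moran's eigenvector maps, all-subsets
    AICc regression, gridded interpolation) that projects process
    influences across a landscape.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    interp,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
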