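Package: plastisphere
Title: Community Assembly and Succession Analysis for Plastisphere Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spatiotemporal succession of microbial
    communities colonising plastic substrates (the plastisphere) and of the
    surrounding water fractions. Implements alpha diversity (richness, Faith's
    phylogenetic diversity), pairwise beta-diversity partitioning of Sorensen
    dissimilarity into species turnover and nestedness with the beta-ratio
    statistic, phylogenetic null models (beta mean nearest taxon distance,
    beta nearest taxon index) and Raup-Crick with Bray-Curtis, classification
    of sample pairs into ecological assembly processes (selection, dispersal,
    drift), time-decay of community similarity, PERMANOVA and Mantel
    inference, and a convergence-trend statistic. Ships a synthetic
    multi-lake, multi-polymer, multi-timepoint community generator with known
    assembly regimes so every stage can be exercised and calibrated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    permute,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
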