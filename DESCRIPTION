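Package: trophgrad
Title: Trophic Associations and Abiotic Drivers of Microbial Communities
    Along Environmental Gradients
Version: 0.1.0
Authors@R:
    person("Paddy", "Soils", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how abiotic gradients and putative trophic
    associations (protist-bacteria, virus-bacteria) structure soil bacterial
    communities. Provides ASV table handling (rarefaction, prevalence
    filtering, relative abundance), a synthetic-data generator with planted
    latitudinal gradients and predator-prey links, alpha/beta diversity and
    ordination statistics (NMDS, ANOSIM, Mantel, distance-decay),
    random-matrix-theory thresholded bipartite co-occurrence networks with
    per-site subnetwork metrics, a normalized stochasticity ratio (NST) with
    occupancy-proportional null models, distance-based redundancy analysis
    with VIF pruning, hierarchical and variation partitioning over predictor
    groups, moving-window scans along a gradient, Procrustes/PROTEST
    ordination congruence, and AIC-selected gradient trend models, plus a
    pipeline orchestrating the survey and microcosm analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
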