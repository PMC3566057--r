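Package: phyloenm
Title: Phyloclimatic Analysis of Ecological Niche Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative phyloclimatic analysis:
    presence-background ecological niche models with RAW (unit-mass)
    suitability output, Schoener's D and Hellinger-based I niche overlap
    statistics, predicted niche occupancy (PNO) profiles, maximum-likelihood
    Brownian-motion reconstruction of climatic tolerances on a dated
    ultrametric phylogeny, and disparity-through-time analysis with the
    morphological disparity index (MDI), whole-tree and per clade.  Includes
    a synthetic-data generator (spatially autocorrelated climate fields,
    Yule trees, Brownian niche optima, suitability-weighted occurrence
    sampling) so the full pipeline runs and is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    withr,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
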