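Package: sdmgap
Title: Ensemble Species Distribution Models and Protected-Area Gap Analysis on
    Synthetic Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for assessing how well a
    protected-area (PA) network covers species ranges under current and future
    climate. Generates synthetic worlds (spatially autocorrelated bioclimatic
    layers, virtual species with known Gaussian niches, biased presence-only
    sampling, a PA network with IUCN-style classes, zoogeographic-region and
    country partitions), cleans and thins occurrence records, fits per-species
    ensemble species distribution models (GLM, boosted trees, MaxEnt-style
    regularized logistic regression, random forest, SVM) with TSS-weighted
    averaging and maxTSS binarization, projects no-dispersal future ranges,
    and computes PA-effectiveness metrics (coverage fractions, benchmark
    proportions, rarity-weighted richness, range loss inside versus outside
    PAs with Wilcoxon tests) and conservation-priority/gap maps with
    country-level accounting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    ranger,
    xgboost,
    glmnet,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
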