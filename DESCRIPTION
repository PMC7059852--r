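Package: shallowmeta
Title: Coverage-Reduction Analysis of Shotgun Metagenomics Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate how far the sequencing depth of a shotgun
    metagenomics experiment can be reduced before taxonomic summaries
    degrade. Implements detection-threshold calibration against a staggered
    mock community (confusion counts and F1 score), replicated read
    subsampling by multivariate hypergeometric draws with confidence bands,
    alpha-diversity depth curves (observed taxa, Shannon, Pielou),
    full-versus-reduced abundance correlation, beta-diversity stability via
    Procrustes superimposition with a permutation test, and a synthetic
    community/classifier simulator (staggered compositions, sister-species
    misclassification, gene recovery under a Lander-Waterman coverage
    model) so the whole pipeline runs without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
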