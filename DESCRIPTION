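Package: dispersalTraits
Title: Movement, Assay and Morphometric Analysis of Dispersal Selection Lines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the behavioural and morphological traits
    that accompany experimentally evolved dispersal in flour beetles.
    Provides S4 containers for multi-animal trajectory recordings, the three
    replicate-level activity metrics (path-length rate, Benhamou sinuosity
    via constant-chord path rediscretization, and arena edge affinity),
    scoring of dispersal and surface-affinity assays, repeatability screening
    and correlation-matrix PCA of morphometric traits, a battery of
    fixed/mixed regime-comparison models with pairwise contrasts and
    interaction pruning, and a fully seeded synthetic-data generator
    (bounded correlated random walks, binomial assays, latent-factor
    morphometrics) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    lme4,
    lmerTest,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
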