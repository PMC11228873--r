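Package: phenomGP
Title: Phenomic and Genomic Prediction from Temporal Drone Vegetation Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-environment phenomic and genomic prediction for maize
    grain yield and plant height from temporal drone-derived vegetation
    indices. Implements two-stage analysis of randomized complete block
    trials: stage one extracts hybrid BLUEs and hybrid-by-flight temporal
    BLUPs with REML mixed models; stage two summarizes temporal curves by
    functional principal component analysis so that phenomic data from
    environments with mismatched flight schedules can be merged, builds
    genomic, phenomic, environment and Hadamard interaction relationship
    kernels, and fits six Bayesian kernel regression models (including a
    bivariate multitrait model with a secondary phenomic trait) by Gibbs
    sampling. Includes four cross-validation scenarios for tested and
    untested hybrids in observed and unobserved environments, and a
    synthetic multi-environment trial generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
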