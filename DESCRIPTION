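Package: methmetrics
Title: Methane Emission Metrics for Pasture-Based Sheep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derivation and comparison of absolute, ratio-based and residual
    enteric-methane traits in sheep measured with portable accumulation
    chambers (PAC). Provides a synthetic flock generator with configurable
    variance components and breed structure, the data-editing rules used for
    PAC phenotype datasets, crossbreeding covariates (heterosis, recombination
    loss, metabolic body weight, average daily gain), twelve ratio traits
    (methane intensities, methane yield, carbon-dioxide based ratios), a
    linear mixed-model engine (EM-REML via Henderson's mixed-model equations)
    for residual methane traits, repeatability and estimated marginal means,
    and record-level correlation and top-quartile selection-ranking reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
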