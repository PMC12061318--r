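Package: envirogs
Title: Envirotype-Aware Genomic Selection with Reaction-Norm Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for environment-aware genetic analysis and genomic
    prediction in multi-environment crop trials. Daily weather is converted
    into nine environmental parameters (growing degree days, photothermal
    time and ratio, diurnal temperature range and related quantities),
    reduced to developmental-stage windows along the cumulative thermal-time
    axis, and screened for critical stage windows whose means drive trait
    environment means. Per-genotype reaction norms on those windows yield
    phenotypic-plasticity intercepts and slopes; variance decomposition and
    broad-sense heritability summarise genotype, environment and interaction
    contributions. Marker features are assembled from trait-associated
    markers with linkage-disequilibrium or fixed flanks, and a stacked
    ensemble of gradient-boosted trees and Bayesian ridge regression is
    tuned, trained and evaluated under five-fold cross-validation and three
    cross-environment/cross-genotype prediction scenarios. A synthetic
    multi-environment-trial generator with known reaction-norm architecture
    supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    lme4,
    jsonlite,
    yaml,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
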