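Package: bmitails
Title: Polygenic Simulation and Inference for Extreme-Sampled BMI
    Case-Control Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and inference toolkit for genetic studies that
    contrast clinically ascertained extremes of the BMI distribution, such
    as persistent healthy thinness versus severe early-onset obesity. An
    additive polygenic simulator generates Hardy-Weinberg genotypes and
    standardized phenotypes, truncates the lower tail, and samples
    asymmetric extreme case-control cohorts; an ensemble of such
    simulations provides the empirical null for a per-locus
    deviation-from-additivity test on the odds-ratio scale. Further stages
    cover weighted standardized genetic risk scores with proportional and
    partial-proportional-odds cumulative-logit regression and
    simulation-based empirical p-values, direction-of-effect binomial
    enrichment tests, inverse-variance fixed-effect meta-analysis with
    Cochran's Q heterogeneity, a three-criterion replication filter, and
    observed-to-liability-scale heritability conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    MASS,
    metafor,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
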