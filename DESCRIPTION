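Package: dyadmr
Title: Dyadic Mendelian Randomisation for Spousal Trait Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying trait concordance within couples using
    genetic instruments. Provides a synthetic couple-cohort simulator with
    assortative-mating, partner-interaction and shared-environment scenarios;
    spouse-pair reconstruction from household descriptors and parent-pair
    reconstruction from identity-by-descent sharing; questionnaire and
    accelerometer sleep-trait encoders; covariate-adjusted cross-partner
    correlations; unweighted genetic risk scores with instrument-strength
    diagnostics; one-sample cross-partner Mendelian randomisation (two-stage
    least squares, IVW, MR-Egger, least-absolute-deviation, Sargan test); and
    fixed/random-effects meta-analysis with heterogeneity statistics for
    sex-combination and effect-modification analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    metafor
Config/testthat/edition: 3
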