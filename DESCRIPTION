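Package: metstab
Title: Mixed-Model Stability Selection for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of multi-environment trials (MET) with linear mixed
    models: REML estimation of variance components with likelihood-ratio
    tests for random terms and a fixed-genotype ANOVA; BLUP-based genotypic
    values; singular-value decomposition of the genotype-by-environment
    interaction (GEI) BLUP matrix into interaction principal component axes;
    the WAASB stability index (weighted average of absolute IPCA scores) and
    the WAASBY yield-stability superiority index; a multi-trait stability
    index (MTSI) built on factor analysis of the genotype-by-trait WAASBY
    matrix with ideotype distances, selection differentials and gains; and
    the harmonic-mean/relative-performance family of genotypic-value indices
    (HMGV, RPGV, HMRPGV). Includes a synthetic randomized-complete-block MET
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
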