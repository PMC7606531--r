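Package: svfscore
Title: Family-Level Social Vulnerability Scoring for SUDI Epidemiology
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a family-level Social Vulnerability Framework for
    sudden unexpected death in infancy (SUDI) research: a 32-indicator
    ledger with family-structure, within-family prevalence and persistence
    weighting rules yielding a simple summation score (0-32) and a
    family-weighted composite score (0-63); exploratory factor analysis of
    the binary indicators with varimax rotation to recover three orthogonal
    vulnerability types (chaotic lifestyle, socioeconomic, psychosocial);
    nonparametric risk-factor association analysis (Wilcoxon/Kruskal-Wallis
    tests, Hodges-Lehmann location-shift estimates with confidence
    intervals, cumulative risk-factor regression); and a seeded synthetic
    cohort generator with a planted latent-factor structure so the whole
    pipeline is testable without confidential coronial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    broom
Config/testthat/edition: 3
RoxygenNote: 7.3.3
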