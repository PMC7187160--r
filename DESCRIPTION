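Package: atrophypower
Title: Multicenter Trial Power Analysis for Regional Brain Atrophy Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning multicenter clinical trials that use regional
    brain volumes as outcome measures, motivated by premanifest Huntington
    disease. Generates synthetic longitudinal multicenter cohorts with nested
    center/participant variance structure, adjusts regional volumes for
    covariates with nested random-intercept linear mixed models, computes
    cross-study standardized effect sizes with bootstrap confidence intervals
    and a medium-effect selection rule, and estimates statistical power and
    sample-size thresholds for hypothetical disease-modifying treatment
    effects by Monte-Carlo simulation over trial design grids.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
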