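Package: lifehaz
Title: Survival and Age-Specific Hazard Analysis for Censored Colony
    Lifespan Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Demographic analysis of right-censored lifespan records from
    captive animal colonies, built around the question of whether mortality
    hazard rises with age.  Parses colony spreadsheets whose dates may be
    recorded at day, month, season, year, range or inequality resolution
    and imputes them with a deterministic midpoint hierarchy; estimates
    Kaplan-Meier survival and age-binned per-day mortality and censorship
    hazards from exposure days, with continuity-corrected Wilson score
    intervals; fits constant-hazard and Gompertz-Makeham mortality models
    by censoring-aware maximum likelihood; simulates cohorts day by day
    under age-binned death and censorship probabilities, including
    breeder/non-breeder mixtures and simulation-ensemble survival
    envelopes; and ingests species life tables for cross-species hazard
    comparison on a reproductive-maturity-rescaled age axis.  A synthetic
    colony-record generator with known ground truth supports end-to-end
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
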