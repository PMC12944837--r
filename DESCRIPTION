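Package: cosmetrisk
Title: Probabilistic Health-Risk Assessment of Heavy Metals in Cosmetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for survey-based health-risk analysis of metal impurities
    in cosmetic products. Provides a data model for left-censored
    concentration measurements (non-detects at metal-specific limits of
    detection, imputed as LOD/sqrt(2)), detection-rate and censored
    descriptive summaries, guidance-value exceedance screening, varimax-rotated
    principal component analysis for source characterization, the dermal
    systemic exposure dose (SED), hazard quotient (HQ) and lifetime cancer
    risk (LCR) equations, and a two-dimensional Monte Carlo engine separating
    concentration variability from body-weight uncertainty. A synthetic
    survey generator with planted correlation structure and an adulteration
    mixture makes the full pipeline testable without access to raw
    measurement data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
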