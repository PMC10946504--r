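Package: metaits
Title: Meta-Analysis of Interrupted Time Series Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-stage meta-analysis of interrupted time series
    (ITS) studies and for Monte Carlo evaluation of the statistical methods
    involved. Simulates segmented-regression ITS data with lag-1
    autocorrelated errors and between-study heterogeneity; fits
    segmented linear regressions by ordinary least squares, Prais-Winsten,
    or restricted maximum likelihood (REML) with a fallback cascade; pools
    study-level level-change and slope-change estimates with fixed-effect
    and random-effects models (DerSimonian-Laird and REML between-study
    variance estimators; Wald-type and Hartung-Knapp/Sidik-Jonkman
    confidence intervals); and summarises simulation performance (bias,
    coverage, empirical and model-based standard errors, power) with
    Monte Carlo standard errors. Includes a worked meta-analysis of
    published state-level traffic-fatality effect estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    nlme,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
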