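Package: samort
Title: Small-Area Mortality Estimation Under Incomplete Death Registration
    with Probabilistic Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates age- and sex-specific mortality rates for small areas
    whose vital-registration systems miss a fraction of deaths, and forecasts
    them probabilistically. Implements the TOPALS relational model (penalized
    Poisson likelihood on linear B-spline offsets to a standard log-mortality
    schedule), a Bayesian model that couples the TOPALS likelihood with Beta
    priors on age-patterned death-registration coverage to recover adjusted
    rates and completeness schedules, Marshall's local empirical-Bayes spatial
    smoothing, single-year life tables with lifespan-variability summaries,
    and an adapted Lee-Carter forecast in which each small area keeps its own
    jump-off schedule while borrowing the regional age response and mortality
    index. A synthetic-data module generates geographies, true schedules,
    under-registered death counts and regional rate histories with known
    ground truth so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
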