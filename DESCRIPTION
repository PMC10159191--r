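Package: rayvisits
Title: Visitation Analysis of Acoustically Tagged Rays at Shellfish Aquaculture Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for passive acoustic telemetry visitation analysis of
    durophagous rays (whitespotted eagle rays and cownose rays) monitored at
    shellfish aquaculture leases and nearby reference receivers. Provides
    detection-log import and false-detection filtering, diel, tidal, lunar and
    environmental annotation, rate-of-movement-derived residence ("visit")
    extraction with a configurable time-out, detection and visit summary
    tables, Poisson generalized linear mixed models of detection counts with
    Tukey-adjusted contrasts, Gamma generalized additive mixed models of visit
    duration with collinearity screening and AICc subset selection, and a
    seeded synthetic telemetry generator with known ground truth for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    lubridate,
    rlang,
    stats,
    utils,
    lme4,
    mgcv,
    emmeans,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
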