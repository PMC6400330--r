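Package: pagephen
Title: Seasonality Detection in Daily Pageview Time Series
Version: 0.1.0
Authors@R:
    person("Open", "Contributor", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects seasonal patterns in daily count time series of online
    interest in species, such as Wikipedia pageviews. Implements a per-page
    classification pipeline (LOESS smoothing with AICc span selection,
    year-over-year annual-consistency regression, linear detrending, and
    harmonic regression with one or two annual peaks selected by
    log-likelihood), a Tukey biweight minimum-traffic filter, species-,
    class- and language-level aggregation with latitude regression and
    monthly rank-popularity trajectories, and concordance testing between
    monthly pageview totals and monthly observation frequency with
    Benjamini-Hochberg false-discovery-rate control. A synthetic-data
    generator with known ground truth (negative-binomial counts around a
    log-scale trend plus sinusoidal signal and spike events) makes every
    stage testable without external downloads.
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
    withr,
    jsonlite
Config/testthat/edition: 3
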