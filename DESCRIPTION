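Package: dfu
Title: Distance from Unimodality for Ordinal Opinion Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures opinion polarization on ordinal rating histograms with
    the distance-from-unimodality (DFU) statistic: the largest adjacent-bin
    violation of the monotone-around-the-mode rule, zero exactly for unimodal
    (including uniform) distributions. Ships the classical dispersion
    baselines it is compared against (standard deviation, Leik's ordinal
    consensus D, the d-squared index, kurtosis peakedness), Gaussian-mixture
    simulators for stress-testing, aggregation of multi-rater ordinal
    annotations with a country-diversity resampling analysis, discretization
    of continuous sentiment scores into daily polarization time series with
    peak flagging, and correlation of all measures against gold human
    polarization judgments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
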