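Package: kinabund
Title: Close-Kin Mark-Recapture Abundance Estimation from a Single
    Sampling Event
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating reproductive female abundance in small,
    stage-structured wildlife populations from kin pairs found in a single
    (one-time) sampling event. Provides an individual-based, female-only
    demographic simulator for a birth-pulse species with stage-specific
    breeding and survival, tabulation of calf x potential-mother pairwise
    kinship comparisons, a stage-stratified multinomial pseudolikelihood
    estimator of abundance with 95% profile-likelihood confidence
    intervals, a simulation-study engine summarising bias, precision and
    interval coverage over grids of population size and sampling fraction,
    and a single-year binomial estimator for annual field surveys, bundled
    with the Tonquin (Jasper National Park) woodland caribou survey counts
    as a worked case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
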