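Package: mvexcess
Title: Multiverse Estimation of Relative Excess Mortality
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates relative excess deaths (P-scores) for national
    age-stratified mortality data under every admissible reference
    baseline window, rather than a single analyst-chosen baseline.
    Expected deaths are computed by averaging age-band mortality rates
    over each consecutive-year baseline window and applying them to the
    projected period's age-band populations; the resulting multiverse of
    estimates is summarized, optionally down-weighting older reference
    years, and used to study cross-country rank stability, worst
    historical periods, and the attenuation of pandemic mortality peaks
    as the projected period lengthens. Includes readers for weekly
    short-term mortality fluctuation files and annual 1-year-age archive
    files, a synthetic-demography generator for testing, and a
    command-line interface.
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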