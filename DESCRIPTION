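Package: sdtvalue
Title: Expected Value and Subjective Utility of Signal-Detection Decision Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for decision modeling at the intersection of signal
    detection theory and behavioral economics. Values discrete gambles under
    expected-value, utility, and prospect-theory rules; computes the
    signal-detection expected-value function over decision-criterion
    locations for Gaussian target/foil environments with a four-entry payoff
    matrix and base rate; finds optimal criteria by grid refinement or the
    closed-form likelihood-ratio solution; extends the expected-value
    function with prospect-theory value and probability-weighting functions;
    characterizes payoff variability as an expected-value envelope; and
    simulates criterion-based observers with maximum-likelihood parameter
    recovery (d-prime, criterion, beta).
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
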