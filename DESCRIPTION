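Package: tdcea
Title: Cost-Effectiveness Analysis of Travelers' Diarrhea Management During
    Military Deployment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree cost-of-illness model for acute watery diarrhea
    (travelers' diarrhea) in deployed military populations. Evaluates the
    expected annual duty days lost (DDL) and management cost of an eight-leaf
    care-pathway tree, compares hypothetical management strategies (increased
    health-care-seeking behavior, optimized provider prescribing behavior, and
    their combination) via DDL-averted and cost-effectiveness ratios, and
    quantifies parameter uncertainty with one-way (tornado) sensitivity
    analysis and Monte Carlo probabilistic sensitivity analysis using
    triangular and truncated-normal parameter distributions. Includes a
    per-episode microsimulator that serves as a brute-force check on the
    deterministic expectations.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
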