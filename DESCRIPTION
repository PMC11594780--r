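Package: czeis
Title: Graphic Indexes and Nonparametric Reference Intervals for
    Capillary Electrophoresis Immunosubtraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies capillary zone electrophoresis-immunosubtraction
    (CZE-IS) curves for monoclonal gammopathy screening. Computes five
    graphic indexes per electrophoretic zone (finite-difference peak
    sharpness, kappa/lambda light-chain ratio, and IgG/IgA/IgM
    immunosubtraction differences), establishes and validates
    nonparametric 95% reference intervals following the CLSI EP28-A3c
    procedure (D/R one-third outlier rule with sample complementation,
    rank-based percentile limits, exact binomial 90% confidence
    intervals of both limits, binomial transference validation), and
    interprets index panels against the intervals. Ships a seeded
    electropherogram simulator producing labelled six-channel trace
    sets so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
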