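Package: ccnorm
Title: Cohort-Based Normative Modelling and Partial Least Squares
    Correlation for Corpus Callosum Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying structural development of the corpus callosum
    in very preterm (VPT) versus full-term (FT) children from derived
    tractometry feature tables (5 callosal partition volumes and 7 tract
    segments of FA, MD, NDI and ODI). Implements cohort-based age-normative
    modelling with LOESS trajectories, age-bin norms and W-score deviation
    maps; partial least squares correlation (PLSC) between clinical and
    structural blocks with permutation testing of singular values and
    bootstrap loading stability; Table-1 style descriptive group statistics;
    and a synthetic cohort generator with planted ground truth for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
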