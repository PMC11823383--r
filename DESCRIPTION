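Package: isobolr
Title: Fixed-Ratio Isobolographic Analysis of Drug-Drug Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Log-probit dose-response modelling and type I fixed-ratio
    isobolographic analysis of two-drug combinations in cell viability
    assays. Fits probit-versus-log10(dose) lines to plate data, derives
    IC50 estimates with delta-method standard errors, tests parallelism
    of concentration-response curves, computes theoretical additive IC50
    values (a single value for parallel curves, lower/upper bounds from
    dose-equivalence isoboles for non-parallel curves), and classifies
    interactions as synergistic, additive or antagonistic with the
    unpaired Welch t-test. Includes a signed causal-network path
    enumerator for connecting the molecular targets of the combined
    drugs, and a synthetic 96-well viability-plate generator with a
    tunable Loewe interaction index for end-to-end validation.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
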