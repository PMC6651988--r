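Package: synthgap
Title: Synthetic Control Evaluation of Policy Effects on City-Year Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative case studies of a single treated unit on
    annual panel data: synthetic control estimation with simplex-constrained
    donor weights and nested optimization of predictor importance weights,
    donor-pool outcome-level adjustment, in-space placebo permutation inference
    with MSPE-ratio filtering and a pseudo p-value, and a
    difference-in-differences cross-validation regression. Includes a
    factor-model (interactive fixed effects) panel simulator with known ground
    truth, broom-style tidiers, and ggplot2 visualizations of counterfactual
    trajectories, gaps and placebo distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    pracma,
    jsonlite,
    yaml,
    withr,
    sandwich,
    lmtest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
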