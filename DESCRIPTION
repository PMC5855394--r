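Package: strokecea
Title: Cost-Effectiveness Modelling of Mechanical Thrombectomy for Acute
    Ischaemic Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-tree plus three-state Markov cohort model for
    cost-utility analysis of endovascular mechanical thrombectomy added to
    intravenous thrombolysis in acute ischaemic stroke, parameterised for
    the Chinese healthcare setting (2013 CNY). Provides the base-case
    cohort engine with half-cycle correction and discounting, one-way
    deterministic sensitivity analysis with tornado ranking, hypothetical
    efficacy-by-price scenario grids, probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves, and an individual-level
    microsimulation oracle for validating the cohort engine. All results
    are returned as tibbles and plotted with ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
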