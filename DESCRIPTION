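Package: aktpi
Title: Kinetic Modelling of PI3K/AKT-Phosphoinositide Cycle Crosstalk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic mass-action and Michaelis-Menten kinetic
    modelling of the insulin-triggered PI3K/AKT signalling cascade coupled
    to the phosphatidylinositol second-messenger cycle. Builds the
    integrated crosstalk reaction network and its PI3K/AKT-only reduction,
    integrates them with a stiff adaptive solver, encodes GSK3beta-targeted
    drug interventions (initial-concentration modulation and reversible
    competitive inhibitor binding parameterised by Ki or IC50), and reports
    concentration-time exposure integrals, phospho-percentages and relative
    activity in scenario comparison tables. Includes a synthetic
    initial-condition fixture generator and a perturbed-ensemble robustness
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    withr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
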