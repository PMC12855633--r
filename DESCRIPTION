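Package: ionbudget
Title: Element Budgets, Proton Loads and Trend Detection for Long-Term
    Forest Deposition Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for input-output element budgets of intensively
    monitored forest plots. Computes annual ion fluxes in charge
    equivalents from sampling-period solution chemistry and daily water
    fluxes for bulk precipitation, throughfall and seepage; estimates dry
    deposition as the throughfall minus bulk difference; derives the
    proton load of the topsoil from a stoichiometric accounting of
    nitrogen transformations and the buffered percentage; tracks the
    cumulative topsoil sulfur storage balance and detects remobilization
    windows from polynomial trend lines with a mean-absolute-error
    fluctuation threshold; and harmonizes emission inventories on a molar
    basis with sulfur-to-nitrogen ratio tracking. Includes a seeded
    synthetic monitoring-data generator with known ground truth for
    parameter-recovery testing.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
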