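Package: rhsa
Title: Reproductive Health Sub-Account Expenditure Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a reproductive-health sub-account (RHS) from
    public budget ledgers in the National Health Accounts tradition. Implements
    the three standard estimation strategies for settings with weak financial
    information systems: pass-through of funds earmarked for reproductive
    health; apportionment of non-earmarked facility funds with distribution
    factors derived from bottom-up unit-cost expenditure estimates (service
    volumes times unit costs); and apportionment of national administrative
    spending by the direct reproductive-health expenditure ratio. Includes
    constant-currency deflation and purchasing-power-parity conversion,
    agent/provider/function report tables with the conventional
    "amount (share)" presentation, per-capita indicators, a synthetic-ledger
    generator with known ground-truth allocations for validation, and a
    bundled fixture of published Burundi 2010-2012 sub-account tables.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
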