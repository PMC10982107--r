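Package: n2opair
Title: Isotope Pairing Analysis of N2O and N2 Isotopologues from 15N
    Tracer Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions sealed-vial 15N tracer incubation time series into
    biomass-specific anammox, N2O-production and N2O-consumption activities
    using the isotope pairing technique. Provides the binomial pairing
    forward model for N2 and N2O isotopologues (28/29/30 N2, 44/45/46 N2O),
    least-squares slope estimation over a fixed incubation window, the
    inversion equations from observed isotopologue slopes to process rates,
    Henry's-law gas-liquid partitioning including the headspace-equilibration
    method for dissolved N2O, reactor nitrogen-balance summaries, and a
    seeded synthetic vial and reactor data generator so the full pipeline is
    testable without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
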