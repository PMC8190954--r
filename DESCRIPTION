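Package: solcycle
Title: Intrinsic Aqueous Solubility via the Sublimation Thermodynamic Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics-based prediction of intrinsic aqueous solubility (log S0)
    through the crystal -> gas -> solution thermodynamic cycle. Converts
    lattice energies and harmonic vibrational/phonon spectra into sublimation
    enthalpies and free energies beyond the 2RT approximation, computes
    hydration free energies from Boltzmann-weighted conformer ensembles or
    from per-lambda free-energy-perturbation samples via the Bennett
    acceptance ratio, and combines the two legs with the appropriate
    standard-state conversions. Includes seeded synthetic-fixture generators
    with analytic ground truths, tidy data-frame interfaces, ggplot2
    diagnostics and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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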