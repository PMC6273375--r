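Package: cocrysol
Title: Cocrystal Solubility Prediction in Solvent/Anti-Solvent Mixtures
    with PC-SAFT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Thermodynamic modeling of pharmaceutical cocrystal solubility
    in solvent/anti-solvent mixtures. Implements the perturbed-chain
    statistical associating fluid theory (PC-SAFT) equation of state with
    Wertheim association, a solid-liquid-equilibrium solubility solver,
    and a solubility-product model for cocrystals, applied to the
    nicotinamide/succinic acid 2:1 cocrystal in ethanol/water,
    ethanol/acetonitrile and ethanol/ethyl acetate mixtures. Includes
    ternary phase-diagram assembly with eutectic location,
    binary-interaction-parameter fitting from saturation data, the
    average-relative-deviation error metric, and a synthetic saturation
    data generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
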