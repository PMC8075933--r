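Package: nmpglove
Title: Glove Efficacy Risk Assessment for Dermal N-Methylpyrrolidone Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for assessing how well chemical-protective gloves reduce
    internal doses of N-methylpyrrolidone (NMP) during paint stripping.
    Converts glove permeation rates (including detection-limit-censored
    measurements) to permeability coefficients, composes glove and skin
    permeability as a Fick's-law series barrier, simulates blood NMP
    concentrations with a flow-limited physiologically based pharmacokinetic
    (PBPK) model aggregating inhalation, dermal-vapor and dermal-liquid
    routes, and characterizes risk through margins of exposure and glove
    protection factors for occupational exposure scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
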