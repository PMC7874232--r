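Package: camflux
Title: Diel Flux Balance Analysis of the C3-CAM Photosynthetic Continuum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based modeling of leaf metabolism across the C3 to
    crassulacean acid metabolism (CAM) continuum. Provides a two-phase (diel)
    stoichiometric model container with SBML import/export, the published
    core-model corrections for diel proton and oxygen accounting, constraint
    scenarios for C3, CAM, CAM cycling and CAM idling, a photon-minimizing
    flux balance analysis stack (FBA, parsimonious FBA and flux variability
    analysis) on a generic linear-programming interface, a light-period CO2
    continuum sweep with linear interpolation of the RuBisCO
    carboxylase:oxygenase ratio, energetics and accumulation reporting, and a
    carbon-annotated synthetic diel leaf model for hermetic testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    boot,
    pracma,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
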