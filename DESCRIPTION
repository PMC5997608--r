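Package: phbsbr
Title: Feast-Famine Sequencing Batch Reactor Simulation for Mixed-Culture PHB Production
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a sequencing batch reactor (SBR) that couples enrichment of
    polyhydroxybutyrate (PHB)-storing mixed cultures with PHB accumulation under a
    feast-famine (aerobic dynamic feeding) regime. Includes a two-guild storage/growth
    kinetic model with substrate inhibition and storage-capacity saturation, a hybrid
    discrete-event/ODE reactor engine with settling selection and a two-tank
    respirometer loop, oxygen-uptake-rate (OUR) signal processing, a feed-on-demand
    pulse-feeding controller driven by dOUR/dt, Cmol stoichiometry and degree-of-
    reduction balances, cycle performance metrics (specific rates, storage yield,
    volumetric productivity), and a synthetic measurement generator for testing the
    analysis path without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
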