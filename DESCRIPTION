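Package: spillimpact
Title: Stochastic Oil-Spill Trajectories, Weathering and Public-Health
    Impact Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, seed-reproducible pipeline for assessing the
    immediate public-health impacts of a catastrophic tanker oil spill:
    Lagrangian surface-oil trajectory ensembles over gridded wind and
    current fields, pseudo-component oil-weathering and clean-up mass
    budgets, single-layer Lagrangian PM2.5 dispersion with 24-hour
    exposure fields, exposure-response health-impact estimation with
    Monte Carlo uncertainty propagation, and downstream fuel, water,
    food-aid and fishery disruption estimators. All stages run on
    synthetic environmental and demographic inputs with the statistical
    structure of reanalysis products, so every stage is verifiable
    without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
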