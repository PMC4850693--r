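Package: wavearc
Title: Noncoplanar Wave-Arc Trajectories, Delivery Simulation and Dose QA for
    O-Ring Linacs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for dynamic wave-arc radiotherapy research on
    O-ring gantry-ring systems: definition, validation and discretization of
    noncoplanar gantry-ring trajectories into beam angles and control points;
    delivery-time simulation under coupled axis-speed and discrete dose-rate
    constraints (conservative planner model and fastest-delivery controller
    emulation with LogFile-style traces); modulation complexity scoring
    (LSV/AAV) of dynamic-MLC arc plans; minimum-3D gamma-index comparison of
    diode-plane measurements against planned volumetric dose; dose-volume and
    plan-quality metrics with paired comparisons; and seeded synthetic
    generators for plans, dose grids and pseudo-measurements so every
    component is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
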