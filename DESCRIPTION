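Package: pdwell
Title: Peritoneal Dialysis Dwell Kinetics: Simulation, Fitting and Model Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for modelling solute and fluid kinetics during a peritoneal
    dialysis dwell. Implements six lumped and pore-level transport models (the
    Garred model and its simplified-Waniewski variant, the Waniewski
    regression model, the unified Graff model with fixed or free
    diffusion-convection weights, and the three-pore model with a dynamic
    fluid compartment and lymphatic absorption), mass transfer area
    coefficient (MTAC) estimation by closed form, linear regression and
    bounded multistart nonlinear least squares, indicator-dilution and
    protein-dilution volume estimation, normalized concentration and volume
    error metrics, ultrafiltration accounting, a synthetic dwell-session
    generator with known ground-truth transport parameters, and a benchmark
    driver that compares all models on a cohort of dwell sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
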