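Package: dopabuff
Title: Simulation and Estimation Toolkit for Levodopa phMRI Hysteresis Mapping
Version: 0.1.0
Authors@R:
    person("dopabuff", "developers", email = "dopabuff@example.org",
           role = c("aut", "cre"))
Description: Simulates regional cerebral blood flow (rCBF) responses to an
    intravenous levodopa infusion in Parkinson disease and recovers the
    effect-site equilibration rate constant k_e (plus EC50 and Hill
    coefficient n) from noisy perfusion-MRI-like time series. Includes the
    infusion regimen arithmetic, a calibrated two-compartment plasma
    concentration generator, the closed-form effect-compartment solution for
    piecewise-linear plasma curves, a sigmoid Emax response model,
    frame-based Gaussian-noise acquisition simulation, two-stage nonlinear
    estimation (global grid/multistart search followed by Metropolis
    posterior sampling), and a parameter-recovery study driver with
    percentile summaries across disease-severity presets, plasma scenarios,
    noise levels and infusion durations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
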