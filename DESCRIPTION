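Package: cartrt
Title: Combined Targeted Radionuclide and CAR T-Cell Therapy Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the joint dynamics of a tumor cell population under
    targeted radionuclide therapy (TRT) and chimeric antigen receptor (CAR)
    T-cell therapy with a three-compartment ordinary differential equation
    model (unirradiated tumor cells, irradiated tumor cells, CAR-T cells)
    using linear-quadratic dose-rate radiobiology for an exponentially
    decaying radionuclide dose rate. Computes simulated survival endpoints
    (progression-free survival, overall survival, time to minimum burden),
    calibrates model parameters to longitudinal bioluminescence-style tumor
    burden cohorts (global joint fits and bounded per-mouse refits),
    generates synthetic mouse cohorts emulating a six-group preclinical
    multiple myeloma experiment, and runs dosing and scheduling scans to
    optimize the timing of combination regimens.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
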