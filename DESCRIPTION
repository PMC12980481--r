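Package: relaxfit
Title: Viscoelastic Material Parameters from AFM Stress-Relaxation Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and inverse analysis of colloidal-probe atomic
    force microscopy (AFM) stress-relaxation experiments on soft hydrogels.
    Models the three-phase protocol (constant-velocity indentation to a force
    trigger, constant-displacement hold, retraction) for a standard linear
    solid in Hertzian contact via the Lee-Radok hereditary integral, extracts
    the relaxation features (F1, F0, t1, t_mid, u_max) from measured or
    synthetic force curves, recovers the material triple (E0, E1, tau) by
    two-stage optimization, and calibrates closed-form surrogate equations for
    rapid parameter estimation over a factorial simulation grid, with error
    surface analysis. Includes a seeded synthetic-data generator and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
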