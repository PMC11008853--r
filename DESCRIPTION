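Package: skinperm
Title: Compartmental Modelling of Transdermal Drug Penetration in
    Microfluidic Skin-on-a-Chip Diffusion Chambers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and calibrating a three-compartment
    diffusion-convection model of percutaneous drug absorption measured in a
    dynamic (perfused) microfluidic diffusion chamber. Provides exact and
    numerical simulation of the linear compartmental system, the input-output
    (eliminated) reparameterization of the model and a constructive structural
    identifiability analysis, multi-start nonlinear least-squares calibration
    of the four transport rates against cumulative penetration curves,
    descriptive two-phase (slow/rapid) kinetic regression, a registry of
    synthetic experiment scenarios (caffeine and anti-inflammatory creams on
    healthy, psoriatic and allergic skin) with a chip-realistic sampling and
    noise model, quality-control exclusion filtering, and tidy CSV input and
    output with a scriptable command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
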