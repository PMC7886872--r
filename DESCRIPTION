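Package: resim
Title: Reduced-Order Simulation of Hepatic Radioembolization Microsphere
    Transport
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale modelling of yttrium-90 microsphere delivery during
    hepatic radioembolization. Generates synthetic hepatic arterial trees
    (Murray's-law branching) and liver segment perfusion phantoms, derives
    perfusion-based outlet boundary conditions, solves a reduced-order (0D)
    pulsatile network flow with laminar Poiseuille closures and Carreau
    shear-thinning viscosity, tracks microspheres through the network with
    Stokes drag and gravity over a four-cardiac-cycle protocol, converts
    per-outlet exit counts into per-segment activity distributions, and
    compares simulated against observed distributions with percentage-point
    differences, Spearman rank correlation and Bland-Altman limits of
    agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
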