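Package: blebflow
Title: Purse Model of Subconjunctival Bleb Filling After Glaucoma Drainage Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Biomechanical model of the subconjunctival fluid pocket ("bleb")
    that forms after glaucoma filtration surgery or drainage-device
    implantation. The conjunctiva is treated as a clamped elastic sheet that
    purses under a constant aqueous inflow against a resistive outflow,
    giving a first-order filling equation with cubic relaxation, an exact
    dimensionless solution, and closed-form characteristic scales for the
    equilibrium height, pressure and filling time. The package provides the
    analytic solution and numerical ODE simulation, nonlinear least-squares
    recovery of model parameters from sampled height/pressure time series,
    seeded synthetic generators emulating bench (silicone membrane) and
    ex vivo (enucleated eye) filling experiments and clinical bleb
    observations, and a nonlinear iso-pressure "traffic-light" grading chart
    that maps bleb radius and height to an estimated pressure zone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    ggplot2,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
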