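Package: nashmet
Title: Nash-Equilibrium Simulation of Liver Energy Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates pathway-structured metabolic networks as a Nash
    equilibrium in which every pathway node minimizes its dimensionless
    Gibbs free energy subject to elemental mass conservation, and the
    nodes are coupled by inter-pathway transport fluxes converged by
    successive substitution.  Ships a rat-liver central-energy-metabolism
    superstructure together with scenario runners for static cold storage
    (4 degrees C, University of Wisconsin solution flush) and warm
    ischemia (37 degrees C), derived observables (ATP content, adenylate
    energy charge, lactate, ammonia, urea, pH), and Monte-Carlo
    propagation of standard-formation-energy uncertainty with
    generalized-gamma distribution fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
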