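Package: chemadapt
Title: Adaptation Kinetics on Clustered Bacterial Chemoreceptor Lattices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic simulation of CheR/CheB-P methylation-demethylation
    kinetics on a hexagonal lattice of clustered chemoreceptors, with enzyme
    tethering, assistance neighborhoods and brachiation, together with the
    corresponding mean-field analytical model with enzyme localization.
    Receptor cooperativity follows an equilibrium Monod-Wyman-Changeux model.
    Includes Goldbeter-Koshland ultrasensitivity analysis with effective
    saturation constants, a linear noise approximation of activity fluctuations
    via the Lyapunov equation with a three-way variance decomposition, and
    in-silico protocols for ligand ramps, step adaptation, enzyme-count scans,
    population sampling with conserved expression ratios, and enzyme
    processivity statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
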