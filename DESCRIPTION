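Package: mwcdrug
Title: MWC Hemoglobin-Oxygen Binding with Slow Quaternary-Selective Drug Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and fitting of oxygen dissociation and association
    curves for red-cell hemoglobin in the presence of a slowly exchanging,
    quaternary-state-selective affinity-modifying drug (voxelotor-like),
    using the two-state Monod-Wyman-Changeux allosteric model extended with
    drug binding and dissociation rates for the R and T conformations.
    Provides the equilibrium partition-function mathematics, a 20-state
    mass-action kinetic model with stiff ODE integration, an emulation of
    Hemox-analyzer pressure protocols including the instrument's min-max
    saturation normalization, a seeded synthetic-data generator, and
    multi-start chi-square fitting that recovers the allosteric constants
    and the four drug rate coefficients from binding curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
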