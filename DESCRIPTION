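Package: dgcswitch
Title: Activation Analysis of Rec-GGDEF Diguanylate Cyclases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the activation of dimeric diguanylate
    cyclases regulated through a coiled-coil linker. Implements a kinetic
    model of c-di-GMP synthesis with rapid-equilibrium substrate binding and
    delayed non-competitive product inhibition (simulation and global
    Levenberg-Marquardt fitting of progress curves), backbone torsion and
    hinge analysis of conformer pairs, rigid-body rotation quantification,
    coiled-coil heptad register assignment with persistent/conditional
    contact classification and lateral register-shift measurement, and a
    census of Rec-GGDEF inter-domain linkers anchored between the receiver
    KP motif and the GGDEF DxLT motif, with heptad-quantised length
    clustering, aligned sequence logos and slippery-repeat scoring.
    Synthetic-data generators with planted ground truth support all analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    deSolve,
    minpack.lm,
    jsonlite,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
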