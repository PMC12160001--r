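Package: solvmode
Title: Microsolvation Structure Preparation and Free Energies of Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preparing cluster-continuum models of reactions in
    solution: sphere-based QM-region construction with whole-solvent-molecule
    inclusion, transition-state normal-mode analysis that identifies actively
    participating solvent molecules, staged pruning of the explicit solvent
    region (large/medium/small QM regions), rigid-rotor/harmonic-oscillator
    thermochemistry with Eyring rates, and a scaled-particle cavity-entropy
    correction to the free energy of activation. A seeded microdroplet
    generator, synthetic transition-state Hessians with prescribed per-atom
    participation, and an analytic toy potential make the full three-stage
    pipeline runnable and testable without any quantum-chemistry engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
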