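Package: specbind
Title: Spectroscopic Analysis of Small-Molecule Binding to Serum Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ligand binding to proteins from steady-state
    optical spectroscopy. Fits Stern-Volmer and modified (double-log)
    Stern-Volmer models to fluorescence quenching titrations, classifies the
    quenching mechanism from the temperature dependence of the quenching
    constant and the bimolecular rate constant, derives binding thermodynamics
    (van't Hoff enthalpy and entropy, Gibbs free energy) from multi-temperature
    binding constants, performs site-marker competitive displacement analysis,
    computes the Forster resonance energy transfer overlap integral, Forster
    radius and donor-acceptor distance, and converts translational diffusion
    coefficients to hydrodynamic radii via the Stokes-Einstein relation.
    Includes a synthetic-data generator with known ground truth so that every
    stage of the pipeline can be validated end to end, and a study driver that
    assembles all stages into a single structured report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
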