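Package: ksbind
Title: Binding-Stability and Energetics Analysis for Ketoreductase-Polyketide Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis layer for molecular-dynamics and docking studies of
    ketoreductase (KR) - polyketide substrate binding. Implements a framewise
    native-contact stability score (fraction of initial-frame heavy-atom
    receptor-ligand pairs within 7 Angstrom that persist), equilibration-window
    extraction and ligand-exit detection; classification of docking poses
    against the front-patch and back-patch substrate-channel entrances with
    frequency tabulation; MM-PBSA binding free-energy decomposition
    (dGvdw = VDWAALS + ENPOLAR, dGele = EEL + EPB) with framewise Pearson
    correlation and representative-replicate selection; a truncated
    Lennard-Jones/Coulomb cross-interaction calculator; grouped Welch t-test
    comparisons with the conventional significance-star scheme; and seeded
    synthetic generators (bound and unbinding trajectories, correlated energy
    tables, pose clouds) so the whole pipeline is testable without running MD
    or docking.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    MASS,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
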