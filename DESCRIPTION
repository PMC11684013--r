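Package: memsig
Title: Membrane-Dependent Receptor Dynamics from MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trajectory-analysis toolkit for quantifying how lipid bilayer
    composition modulates the dynamics of membrane-embedded receptor
    complexes, developed around the NKG2A/CD94/HLA-E inhibitory immune
    receptor. Provides rigid-body superposition and frame windowing,
    RMSD/RMSF/B-factors, dynamic cross-correlation matrices with
    domain-pair correlation densities, mass-weighted essential-dynamics
    PCA, hierarchical conformation clustering, residue-anchored helix
    tilt/crossing and receptor-head bending angles, bilayer electron
    density and peak-to-peak thickness, area per lipid, deuterium order
    parameters, water radial distribution functions, contact and
    hydrogen-bond persistence statistics, and a simplified Kabsch-Sander
    secondary-structure assignment. Includes synthetic-trajectory
    generators with analytic ground truth for validating every
    observable, plus a config-driven analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
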