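Package: hydrafibre
Title: Water Ordering and Self-Assembly Analysis for Peptide-Amphiphile Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for peptide-amphiphile (PA) self-assembly
    simulations with an emphasis on the structure and dynamics of interfacial
    water. Provides readers and writers for PDB, GRO, multi-frame extended XYZ
    and CHARMM/NAMD DCD files; a selection mini-language with periodic
    "within" shells; water-structure metrics (radial distribution functions,
    axial and cylindrical density profiles, Steinhardt Q6, tetrahedral and
    translational order parameters, geometric hydrogen bonds); time-correlation
    analyses (velocity autocorrelation, vibrational density of states, spectral
    band metrics, water residence times); aggregate census tools (PBC-aware
    clustering, micelle/fibre classification, fibre linear density and
    diameter, hexagonal lattice spacing, Ramachandran and chirality analysis);
    multiscale coupling (atom-to-bead forward mapping, bead-to-atom
    back-mapping with exact centre-of-mass restraints, density-targeted water
    reinsertion); and umbrella-sampling free energies (self-consistent WHAM
    with two-temperature enthalpy/entropy decomposition). Seeded synthetic
    generators produce every fixture needed to exercise the pipeline without a
    molecular-dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
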