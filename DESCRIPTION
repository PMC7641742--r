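Package: qdhfold
Title: Restraint-Based Structure Determination of Quadruplex-Duplex Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for NMR restraint-driven structure
    determination of quadruplex-duplex hybrid (QDH) DNA folds, with the two
    coexisting PIM1 promoter structures built in. Provides declarative
    topology models of G-tetrad cores, G.C.G.C tetrads and Watson-Crick
    stems; generation of flat-bottom NOE distance, chi dihedral,
    hydrogen-bond and planarity restraints; metric-matrix distance-geometry
    embedding followed by restrained simulated annealing and minimization;
    ensemble statistics (restraint violations, covalent-geometry deviations,
    pairwise heavy-atom RMSD); two-component circular-dichroism spectral
    decomposition and two-state melting-temperature extraction; and seeded
    synthetic-data generators (idealized coordinates, classed NOE peak
    lists, CD mixtures, melting curves) so that every stage is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
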