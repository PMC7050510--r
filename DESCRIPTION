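Package: permeaR
Title: Conformer-Ensemble QSPR Models of Passive Membrane Permeability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-empirical prediction of apparent passive membrane
    permeability (PAMPA LogPapp) from molecular structure. Molecules are
    prepared as neutral, hydrogen-complete 3D structures; conformer
    ensembles are generated by Monte-Carlo dihedral sampling with ring
    opening/closure under a simplified AMBER-like force field and clustered
    by heavy-atom RMSD to estimate degeneracies; per-conformer water and
    membrane energies from a generalized Born / surface-area model give
    Boltzmann ensemble statistics (mean and deviation of radius, atom-typed
    accessible surface area, intramolecular hydrogen bonds) and a
    partition-function LogD. Three permeability feature layouts (fixed
    conformer during crossing, re-equilibrated conformers, and their union)
    feed a principal-component regression with L2 or L1 regularization,
    with cross-validation, axis selection, and size-stratified hold-out
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    bio3d,
    ChemmineOB,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
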