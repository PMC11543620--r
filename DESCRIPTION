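Package: equiscore
Title: Equivariant Graph Attention Scoring of Protein-Protein Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the quality of docked protein-protein interfaces with an
    SO(3)-equivariant graph attention network operating on residue-level
    complex graphs (coordinates, amino-acid one-hot, a 16 Angstrom interface
    indicator, and pluggable per-residue embeddings). Includes the
    rotation-order feature algebra (real spherical harmonics, Wigner
    rotations, Clebsch-Gordan tensor products), ground-truth interface
    quality metrics (fnat, interface and ligand RMSD, CAPRI classes, DockQ,
    AlphaFold-Multimer ranking confidence and the combined
    confidence-plus-DockQ regression target), a full ranking evaluation stack
    (ROC/AUC, step-wise average precision, threshold-swept MCC and F1, top-N
    hit curves, score ensembling, DeLong AUC comparison with Bonferroni
    correction), and a seeded synthetic rigid-body decoy generator so the
    whole pipeline runs at desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
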