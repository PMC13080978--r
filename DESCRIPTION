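Package: rnapose
Title: Post-Docking Analysis for RNA-Targeted Ensemble Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Curation and interpretation of RNA-ligand ensemble docking
    campaigns. Implements eRMSD and nucleotide g-vectors for comparing RNA
    conformations, Quality-Threshold clustering on arbitrary distance
    matrices with medoid extraction and diversity-based centroid retention,
    symmetry-corrected scaffold RMSD between docked poses of a congeneric
    ligand series, geometric RNA-ligand interaction fingerprints histogrammed
    by contact distance, and principal-component analysis of fingerprints
    with per-cluster regression against experimental affinities. Ships a
    fully seeded synthetic-data generator (idealized RNA helices, perturbed
    conformational ensembles, symmetric-scaffold congeneric ligands, and pose
    sets with planted interaction-affinity structure) so the entire pipeline
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    ChemmineR,
    methods,
    stats,
    utils,
    data.table,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
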