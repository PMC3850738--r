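Package: dockrank
Title: Rescoring, Clustering and Benchmark Evaluation of Protein-Protein
    Docking Poses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating scoring functions on protein-protein
    docking decoy sets. Reads docked poses and native complexes from PDB
    files, computes the CAPRI quality measures (fraction of native
    contacts, interface RMSD and ligand RMSD) and the derived
    incorrect/acceptable/medium/high quality classes, scores poses with
    pluggable residue-level contact potentials (intermolecular or
    separable E_complex - (E_receptor + E_ligand) modes), re-ranks and
    greedily clusters poses at a ligand-RMSD threshold keeping the
    best-scoring cluster representative, and computes per-metric top-N
    success rates, conditional success probabilities stratified by
    docking difficulty, and set-theoretic complementarity (union,
    symmetric difference, relative complement) between scoring functions
    with complete-linkage clustering and cophenetic distances. Includes a
    synthetic benchmark generator with known ground truth for validating
    the evaluation machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
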