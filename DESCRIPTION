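Package: ligdyn
Title: Trajectory-Derived Flexibility Descriptors, Structure Curation and
    Graph Baselines for Protein-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for quantum-chemistry- and molecular-dynamics-
    augmented protein-ligand datasets. Provides a hierarchical (HDF5) data model
    for complexes, trajectories, per-atom quantum properties and affinity
    metadata; trajectory descriptors (per-atom adaptability, RMSF, ligand RMSD
    after protein superposition, centre-of-mass distance, buried solvent-
    accessible surface area); geometry-level structure-curation heuristics
    (steric clashes, distance-based bond and hybridization perception, valence
    and local-charge audits, reference-geometry deviation flags, connectivity
    comparison, property-outlier screening); molecular-graph featurization with
    radius edges and inverse-distance weights; three baseline graph-network
    learners (graph-level quantum-property regression, node-level adaptability
    regression, twin-network relative binding-affinity regression); benchmark
    construction filters, leakage-aware sequence-clustered splitting and
    B-factor/RMSF validation; and seeded synthetic generators so every
    component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    rhdf5,
    jsonlite,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
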