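Package: tripod3d
Title: Three-Graph Geometric Message Passing for Molecular Representation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Molecular representation learning from 3D structure via a
    three-level geometric graph neural network. Molecules are encoded as
    linked atom-bond, bond-angle, and angle-dihedral graphs so that bond
    lengths, bond angles, and signed dihedral (torsion) angles all enter the
    message passing, making the learned embeddings sensitive to absolute
    configuration (chirality). The network is pre-trained with multiscale
    self-supervised tasks: masked prediction of bond lengths, bond angles,
    dihedral angles, and binned interatomic distances from MMFF94 conformers,
    followed by prediction of atomic partial charges and Wiberg-style bond
    orders. Includes scaffold-split fine-tuning with ROC-AUC/RMSE/MAE
    evaluation, stereoisomer and conformer discrimination experiments
    (Kabsch-aligned RMSD, Davies-Bouldin index), and a deterministic
    built-in fixture set with surrogate quantum-chemical labels so every
    stage runs without external downloads. Molecule parsing, conformer
    generation, stereoisomer enumeration, and Murcko scaffolds are delegated
    to RDKit through a bundled Python helper.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with RDKit, on PATH as 'python'
RoxygenNote: 7.3.3
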