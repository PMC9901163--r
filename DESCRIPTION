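Package: ffinet
Title: Force-Field-Inspired Graph Attention Networks for Molecular Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements FFiNet, a force-field-inspired graph attention network
    for molecular property prediction. Atoms aggregate messages from their
    1-, 2-, and 3-hop neighbours along the bonded graph; attention scores are
    computed from OPLS-functional-form expansions of bond distances, valence
    angles, and signed dihedrals, and an axial attention step arbitrates
    between the three hop channels. Includes SMILES/SDF/PDB/mol2 input via an
    RDKit bridge, ETKDG conformer generation, a protein-ligand complex-graph
    extension with typed nonbonded edges, a full training loop (Adam, early
    stopping, masked multitask losses), evaluation metrics, model
    interpretation utilities, and a synthetic-data generator with a
    geometry-defined pseudo-energy target so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
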