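Package: capriqa
Title: Quality Assessment of Predicted Protein Complexes with the CAPRI Protocol
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing predicted models of protein-protein complexes
    against a reference (target) structure using the CAPRI model-quality
    protocol: fraction of native and non-native residue contacts, ligand and
    interface RMSD after optimal rigid-body superposition, ligand
    mis-orientation angle and centre-of-mass displacement, steric-clash
    disqualification, and classification of models into the High, Medium,
    Acceptable and Incorrect quality tiers. Homo-oligomeric targets are
    handled by enumerating candidate interfaces (including crystallographic
    symmetry images) ranked by buried surface area and by matching model
    subunit pairs to target interfaces over chain permutations. Includes a
    sequence-dependent GDT_TS-style score for individual subunits, per-target
    and per-group ranking reports, and a seeded generator of synthetic targets
    and rigid-body decoy populations with analytically known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
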