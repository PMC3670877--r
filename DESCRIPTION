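Package: angrec
Title: Comparative Sequence, Structure and Docking Analysis of the
    Angiotensin Peptide Receptors AT1, AT2 and MAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A reusable pipeline for the comparative analysis of the
    angiotensin peptide receptors AT1, AT2 and MAS against an outgroup
    class-A GPCR (rhodopsin): per-family consensus annotation with a
    residue-class symbol scheme, helix-based GPCR consensus numbering,
    cross-family conservation classification painted onto structural
    models, ligand pose scoring and top-k ranking with a simplified
    nonbonded energy, distance-constrained rigid-body pose generation,
    and trajectory statistics (CA RMSD, per-residue RMSF, average
    structure, inter-residue distance series).  A synthetic-data module
    generates alignments, 7TM CA bundles, pose sets and trajectories
    with planted, recoverable structure so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
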