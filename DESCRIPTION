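Package: resifp
Title: Residue-Level Interaction Fingerprints for Molecular Complexes
Version: 0.1.0
Authors@R:
    person("resifp", "developers", email = "resifp@example.org", role = c("aut", "cre"))
Description: Detects geometrically defined noncovalent interactions
    (hydrogen and halogen bonds, ionic, pi-stacking, pi-cation, metal
    coordination, hydrophobic and van der Waals contacts) between any pair
    of molecular species on a per-residue basis, encodes them as bitvectors
    over frames or poses, and supports Tanimoto similarity, interaction
    frequency, and residue-network analyses. Includes readers for PDB, SDF
    and MOL2 files, a parametric fixture generator producing toy complexes
    at exact geometries, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
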