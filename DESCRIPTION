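Package: phosphoscreen
Title: Docking-Based Screening of Virtually O-Phosphorylated Phenolic Fragment Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Library-generation and pose-triage pipeline for docking-based
    discovery of phosphotyrosine-mimetic ligands of SH2 domains. Filters a
    compound collection down to natural-product-derived phenolic fragments
    (scaffold-tree matching, phenol/molecular-weight/reactive-moiety rules),
    virtually O-phosphorylates the phenolic hydroxyls, orchestrates a
    pluggable docking engine, and triages docked poses by distance criteria
    between the ligand phosphate group and named receptor residues such as
    Arg609 and Lys591 of the STAT3 SH2 domain. Ships a deterministic
    synthetic-fixture generator (toy libraries with planted composition, toy
    receptors and poses with known geometry) so the whole pipeline is
    testable end-to-end without external data or a docking engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    bio3d,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
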