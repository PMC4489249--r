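Package: ligprof
Title: Rule-Based Profiling of Non-Covalent Protein-Ligand Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and reports non-covalent interactions between proteins
    and small-molecule ligands in 3D structures (PDB format). A four-stage
    rule-based pipeline prepares the structure (polar hydrogen placement,
    blacklist-driven ligand selection, binding-site extraction), functionally
    characterizes both binding partners (hydrophobic atoms, hydrogen- and
    halogen-bond donors and acceptors, aromatic rings, formal charge centers),
    matches interacting groups under configurable geometric distance and angle
    constraints, and filters redundant records. Seven interaction types are
    reported at single-atom detail: hydrogen bonds, hydrophobic contacts,
    pi-stacking, pi-cation interactions, salt bridges, water bridges and
    halogen bonds. Results are serialized to parsable XML and flat text, plus
    a plain-text visualization command script. A synthetic-complex generator
    builds minimal PDB fixtures with exact interaction geometry for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
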