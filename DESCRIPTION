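Package: strucstats
Title: Structural Statistics for Protein Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares ensembles of protein structures position by position.
    Reads PDB coordinate files under explicit policies (first model, first
    alternate location, chain autodetection), establishes a residue
    correspondence across the ensemble from residue numbering or from a
    user-supplied multiple sequence alignment, superposes structures by
    least-squares (Kabsch) fitting, and computes alignment-position-indexed
    statistics: Cartesian coordinate fluctuations and average B-factors for
    backbone and sidechain atoms, backbone (phi, psi, omega) and sidechain
    (chi1-chi4) torsion angles with circular means and standard deviations,
    and a complete-linkage hierarchical clustering of conformers using the
    circular distance between selected dihedral angles.  A synthetic chain
    builder generates valid test ensembles from specified torsions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
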