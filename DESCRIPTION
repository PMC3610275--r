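Package: gpcrgeom
Title: Geometry of the TM6/TM7 Micro-Switch Interface in Class A GPCR
    Structures
Version: 0.1.0
Authors@R:
    person("Maintainer", "gpcrgeom", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural analysis toolkit for the transmembrane helix 6/7
    interface of class A G-protein-coupled receptors. Reads single- and
    multi-model PDB structures, assigns Ballesteros-Weinstein generic
    residue numbers by anchoring the conserved CWxP and NPxxY motifs,
    classifies side-chain chi1 rotamers (gauche+/gauche-/trans), measures
    sulfur- and oxygen-donor hydrogen-bond geometry (donor-acceptor
    distance, Cbeta-D...A angle, Asn amide-flip assessment, polar-network
    scans), and profiles proline-kink helix distortion through backbone
    dihedrals and HELANAL-style unit bend and unit twist angles averaged
    over conformational ensembles. Includes a synthetic-structure builder
    for ideal and kinked helical peptides with controlled phi/psi, chi1
    and kink angle, perturbed ensembles, engineered hydrogen-bond
    fixtures and toy alignments, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
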