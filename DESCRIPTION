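Package: pdbSIFt
Title: Interatomic Contact Detection and Structural Interaction Fingerprints for PDB Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies interatomic interactions in macromolecular
    structures. Atoms of a PDB-format structure are typed physicochemically
    (dictionary-driven for standard polymer residues, connectivity-rule-driven
    for hetero groups), all atom pairs within a 5 Angstrom cutoff are
    enumerated with a grid-based spatial index, and each pair receives a
    structural interaction fingerprint (SIFt): one of five mutually exclusive
    distance classes (clash, covalent, van der Waals clash, van der Waals,
    proximal) plus feature bits for hydrogen bonds, weak hydrogen bonds,
    halogen bonds, ionic, metal-complex, aromatic, hydrophobic, carbonyl,
    polar and weak polar contacts. Planar-group interactions are detected at
    the ring and amide level: pi-pi stacking, cation-pi, donor-pi, halogen-pi
    and carbon-pi atom-ring contacts, amide-amide and amide-ring stacking, and
    methionine sulphur-aromatic contacts. Results are aggregated into
    per-residue binary and integer fingerprints and written as tab-separated
    tables. A geometry-exact fixture generator emits minimal PDB files for
    every interaction subtype at ideal and boundary geometries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
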