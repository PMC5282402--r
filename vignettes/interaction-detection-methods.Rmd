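---
title: "Geometry and typing rules behind pdbSIFt"
author: "pdbSIFt maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry and typing rules behind pdbSIFt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdbSIFt)
```

# The model

`pdbSIFt` treats non-bonded interatomic interactions as a classification
problem over atom pairs: every pair of atoms within a 5 Å radial cutoff
receives a structural interaction fingerprint (SIFt) whose first five bits
are a mutually exclusive distance class and whose remaining bits are
independent "feature" interactions gated by atom types and simple
distance/angle criteria. Group-level phenomena that are poorly described by
single atom pairs — π-stacking, amide stacking, sulphur–aromatic contacts —
are detected on perceived planar groups (rings, amides) instead.

The assumptions are those of any geometric contact calculator:

* the input coordinates are meaningful at the ~0.1 Å level (the method does
  not model coordinate uncertainty; van der Waals clashes are reported, not
  repaired);
* protonation is unknown unless hydrogens are modelled, so every angular
  criterion involving hydrogens has an angle-free fallback (`polar`,
  `weak_polar`) and donor/acceptor assignment is deliberately generous
  (histidine leniency, carboxylate oxygens as acceptors);
* covalent structure can be inferred from distances: two atoms are bonded
  when their separation is at most the sum of their covalent radii plus
  0.45 Å (plus any CONECT records), excluding metals, whose coordination is
  not covalence here.

# Pipeline

1. **Parsing** (`readStructure`). Fixed-column PDB via `bio3d`; one model is
   kept (default the first — multi-model selection is done by a text-level
   split so models need not share an atom list); alternate locations are
   resolved to the highest-occupancy conformer, ties broken by alphabetical
   altLoc identifier (deterministic, matches common practice); dropped
   records are logged with reasons. Model numbering is 1-based, the natural
   R convention. Elements missing from columns 77–78 are inferred from the
   atom name with the PDB alignment convention; deuterium is treated as
   hydrogen. Polymer chains are identified by inter-residue connectivity
   (peptide C–N ≤ 1.7 Å, nucleotide O3′–P ≤ 1.8 Å) and the first/last
   residue of each connected segment is marked as a terminus.

2. **Typing** (`assignAtomTypes`). Standard residues are typed from a
   shipped YAML dictionary covering the 20 amino acids, nucleotides, waters
   and main-chain/terminus atoms. Hetero groups are typed by connectivity
   rules over the bond graph — the semantic content of pattern-based typing
   without a pattern engine: any covalently bound oxygen is an acceptor;
   hydroxyl oxygens donate; terminal oxygens on carboxylate/phosphate/
   sulphate groups are negatively ionisable; amide and guanidinium nitrogens
   donate (guanidinium is positive); ring nitrogens without hydrogens
   accept; thiols donate and accept, thioethers accept; Cl/Br/I on carbon
   are halogen-bond donors (fluorine's σ-hole is negligible, so F never
   donates); every H-bond acceptor is a halogen-bond acceptor. Uniform rules
   then add hydrophobes (C/S with no bonded N/O/P, halogens on carbon) and
   weak donors (carbons that are neither carbonyl nor bonded to ≥ 2 N/O).
   The dictionary and rules are editable configuration; the fixture suite
   defines their correctness. Typing recomputes all flags from scratch, so
   it is idempotent.

3. **Terminus correction and leniency.** A C-terminal O or OXT becomes
   {acceptor, negative} even when its sibling is unmodelled — the
   mislabelled-hydroxyl failure mode is impossible by construction. An
   N-terminal N becomes {donor, positive} (proline: donor only with an
   explicit H, it is a secondary amine). With `lenient = TRUE`, His ND1 and
   NE2 are each donor + acceptor; otherwise they follow explicit hydrogens.

4. **Ring and amide perception.** Standard-residue rings come from the
   dictionary (Phe/Tyr one 6-ring, Trp 5+6, His 5-ring, purines 5+6,
   pyrimidines 6). Hetero rings are cycles of size 5 or 6 from a
   spanning-forest cycle basis of the group's bond graph, kept when all
   members are C/N/O/S with at most three heavy neighbours (sp²-like) and
   the RMS deviation from the least-squares plane is ≤ 0.1 Å. The plane
   normal is the eigenvector of the smallest principal moment of the
   centred member coordinates, with its sign fixed deterministically so
   member order cannot flip it; the centroid is the unweighted member mean.
   Amide groups are one per peptide bond (C,O of residue *i*, N of *i*+1),
   per Asn/Gln side chain, and per ligand carbonyl carbon with a bonded
   nitrogen.

5. **Contacts** (`buildContacts`). Neighbour pairs come from a cell-list
   grid index (cubic cells of edge = cutoff, 13 lexicographically positive
   offsets plus the home cell) — equivalent by construction to the
   brute-force double loop, which the test suite keeps as an independent
   oracle. Intra-residue pairs are excluded from reporting; cross-residue
   1–2/1–3 bonded pairs are distance-classified but carry no feature bits,
   as does anything classified `clash` or `covalent` (a bonded pair is not
   "interacting"). Hydrogen positions enter only through the D–H···A and
   C–X···A angle terms.

6. **Aggregation.** The per-residue integer fingerprint counts the
   residue's *atoms* making at least one in-scope contact of each type
   (an atom with three hydrogen bonds counts once); ring and group
   interactions count once per interaction for each parent residue. A
   contact contributes to both endpoint residues — the fingerprint
   describes each residue's environment. The binary fingerprint is
   `count > 0` by definition.

# Thresholds

All defaults live in `inst/extdata/geometry_config.yaml`, are logged by the
CLI under `-v`, and can be overridden wholesale or per-value. Distances in
Å, angles in degrees.

| parameter | default | rationale |
|---|---|---|
| `cutoff` | 5.0 | radial neighbour cutoff; everything beyond vdW overlap but inside it is `proximal` |
| `cov_tol` | 0.2 | half-width of the covalent band around the covalent-radius sum; 0.2 so partial double bonds (peptide C–N, 1.33 Å vs a 1.46 Å single-bond radius sum) classify as covalent, not clash |
| `vdw_comp` | 0.1 | compensation beyond the vdW sum for the `vdw` class and halogen-bond reach |
| `bond_tol` | 0.45 | connectivity-inference tolerance on covalent radius sums |
| `hbond_dist_max` / `hbond_h_dist_max` / `hbond_angle_min` | 3.9 / 2.7 / 90 | donor–acceptor, hydrogen–acceptor and D–H···A gates (HBPLUS-lineage values) |
| `weak_hbond_dist_max` / `weak_hbond_angle_min` | 3.6 / 130 | C–H donors are weaker and more directional; the H···A cap is shared with ordinary hydrogen bonds |
| `polar_dist_max` / `weak_polar_dist_max` | 3.5 / 4.0 | angle-free analogues, insensitive to hydrogen placement |
| `xbond_angle_min` | 120 | σ-hole directionality of C–X···A |
| `ionic_dist_max` | 4.0 | opposite formal-charge centres |
| `metal_dist_max` | 2.8 | first-shell coordination distance |
| `carbonyl_dist_max` | 3.6 | n→π* dipole-pair C···O distance |
| `hydrophobic_dist_max` | 4.5 | apolar carbon/sulphur packing |
| `aromatic_dist_max` | 4.0 | aromatic-atom to aromatic-atom |
| `ring_ring_dist_max` | 6.0 | π–π centroid gate |
| `atom_ring_dist_max` / `atom_ring_angle_max` | 4.5 / 30 | atom over the ring face: centroid distance and off-normal angle |
| `amide_amide_dist_max` / `amide_ring_dist_max` | 5.0 / 4.5 | amide-group centroid gates |
| `met_arom_dist_max` | 6.0 | thioether S to ring centroid |
| `planarity_tol` | 0.1 | RMS out-of-plane maximum for hetero-ring acceptance |

Covalent radii follow the Pyykkö single-bond scale and van der Waals radii
the Bondi scale (with common extensions for metals); both tables are
configuration, not code. Unknown elements fall back to carbon radii with a
warning so they are still distance-classified, but strict lookups are used
wherever an error is more useful.

# Design choices where the design was open

* **π–π geometry labels.** The folded interplanar angle θ is discretised as
  stacked (θ ≤ 30°), tilted, t-shaped (θ ≥ 60°). The taxonomy is this
  package's own; the underlying θ and centroid distance are reported so
  users can re-bin. No lateral-offset gate is applied beyond the centroid
  distance and face angle — the simplest defensible gate; offsets are
  recoverable from the output.
* **Atom–ring subtypes are not exclusive.** A lysine NZ over a ring face is
  both cation–π and donor–π: the flags are independent properties of the
  atom, and the output keeps all that apply.
* **Metal exclusivity.** A metal atom carries only the `metal` flag, so
  metal–anion pairs are typed metal-complex rather than ionic and metals
  never appear as cation–π donors; the metal-complex bit is the more
  specific description.
* **Entity labels.** With a selection active, a contact is `inter` exactly
  when one endpoint is selected, `intra_selection` when both are; an
  unselected pair involving water is `water_bridge_candidate` (bridge
  *analysis* is out of scope, the label only earmarks candidates), anything
  else `intra_nonselection`. Without a selection everything is
  `intra_nonselection`.
* **His rings count as aromatic for π interactions regardless of
  protonation**; the leniency switch affects only donor/acceptor flags.
* **Cys S–aromatic contacts are off by default** (`sulphur_aromatic_residues:
  [MET]`); adding `CYS` enables thiol sulphur–aromatic detection.

# The fixture generator

The generator (`makeFixture`, `fixtureCatalogue`) is the package's synthetic
test surface: for each of the 23 subtypes (5 distance classes, 10 feature
bits, 5 π types, 3 group families) it emits a minimal PDB file whose single
defining geometric parameter sits at an ideal value, at threshold − 0.05 Å
(`boundary_pass`) or at threshold + 0.05 Å (`boundary_fail`). Coordinates
are analytic — regular hexagons for rings, linear D–H···A triads, exact
centroid placements — and the boundaries are derived from the loaded
`GeometryConfig` at generation time, so editing a threshold keeps the suite
self-consistent. Each entry is annotated with the companion subtypes that
physically must co-occur (a stacked benzene dimer necessarily also shows
aromatic-atom, hydrophobic and carbon–π contacts; a hydrogen bond implies
its polar superset), and the tests assert that nothing outside
{intended} ∪ {companions} fires.

What the fixtures emulate is ideal geometry, one interaction at a time.
They do not emulate real structures: no thermal noise, no crowding, no
competing interactions, no missing atoms beyond the specific terminus
cases, no alternate conformers. Passing the suite therefore shows that each
detector's gate sits exactly where the configuration says it does and that
detectors do not cross-fire on clean geometry — not that the default
thresholds are optimal for any particular crystal structure. Threshold
choice on real data remains the user's scientific decision; everything is
exposed in the YAML.

# Numerical notes and degenerate inputs

* Plane fitting uses the eigendecomposition of the 3×3 scatter matrix;
  normals are unit length with the largest-magnitude component made
  positive, so permuting ring atoms or flipping normals cannot change any
  folded angle (verified to 1e-6 degrees in the tests).
* Contact tables are sorted by (serial_a, serial_b) with endpoints ordered
  by serial, so identical input and configuration produce byte-identical
  TSV output.
* Distances are reported to 3 decimals and angles to 1 decimal in the TSV
  writers; internal computation is double precision throughout (a rigid
  motion applied with `transformStructure` changes contact distances by
  < 1e-12 Å).
* Collinear C/O/N triples (no amide plane), rings with missing member
  atoms, halogens without a bound carbon, and elements without radii
  entries are all handled by skipping the affected record with a warning
  rather than failing the run.
* A single-residue polymer segment is both termini at once and receives
  both corrections.

# Problem sizes in the checks

The shipped verification suite runs the 69-entry fixture catalogue end to
end, compares the grid index with the brute-force double loop on 100 random
clouds of 20–60 atoms, and checks distance-class exclusivity on the
catalogue plus 100 random 50-atom structures — sizes chosen to exercise
every code path many times while keeping the whole suite interactive
(seconds, not minutes). The spatial index is O(n) per atom at fixed
density and has been used on full-size PDB entries; nothing in the method
is specific to small inputs.

# Known limitations

* PDB v3.3 fixed-column input only; no mmCIF, no accession fetching.
* No hydrogen placement or protonation prediction: geometric hydrogen-bond
  bits require modelled hydrogens, which is why the polar/weak-polar
  fallbacks exist and are reported alongside.
* Hetero-group typing is rule-based over inferred connectivity; exotic
  ligand chemistry (delocalised charges, organometallics, unusual oxidation
  states) may type approximately. The dictionary and rules are
  configuration, and the fixture suite is the contract.
* Water-mediated bridge analysis, energy scoring and interaction-strength
  weighting are out of scope; water contacts are reported like any others.
* Aromaticity of hetero rings is geometric (planarity + sp²-likeness), not
  electronic: a perfectly planar non-aromatic ring would be accepted, a
  strongly puckered aromatic rejected.
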