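# pdbSIFt

Interatomic contact detection and structural interaction fingerprints (SIFts)
for macromolecular structures in PDB format.

Molecular recognition — a drug in its binding pocket, two proteins at an
interface, a transcription factor on DNA — is mediated by specific pairwise
interatomic interactions that can be classified from atom types plus distance
and angle criteria. `pdbSIFt` enumerates and classifies these interactions
for any mix of protein, nucleic acid, small-molecule, metal and water atoms,
for the whole structure or for a selected entity (a ligand and its binding
site, one chain against another). It is aimed at structural biologists and
computational chemists who want an auditable, scriptable account of every
contact a structure makes.

## What it computes

Every atom is first typed physicochemically — hydrogen-bond donor/acceptor,
weak (C–H) donor, positive/negative ionisable, hydrophobe, aromatic, halogen
(σ-hole) donor/acceptor, metal, carbonyl C/O — from a residue dictionary for
standard polymers and from connectivity rules over the inferred covalent bond
graph for hetero groups. Any covalently bound oxygen counts as an acceptor
(carboxylates are not excluded), incompletely modelled termini are corrected
from the dictionary (a lone C-terminal O is a carboxylate, never a hydroxyl),
and a leniency switch types both histidine ring nitrogens as donor+acceptor
to absorb tautomeric ambiguity.

All atom pairs within 5 Å are then enumerated with a grid spatial index and
each pair receives a SIFt:

* **one of five mutually exclusive distance classes**, from the covalent
  (`r_cov,i + r_cov,j ± t_cov`) and van der Waals (`r_vdW,i + r_vdW,j`)
  radius sums: `clash`, `covalent`, `vdw_clash`, `vdw`, `proximal`;
* **ten feature bits**: hydrogen bond (D···A ≤ 3.9 Å, H···A ≤ 2.7 Å,
  ∠D–H···A ≥ 90°), weak hydrogen bond (C–H donor, 3.6 Å / 130°), halogen
  bond (X···A within vdW + 0.1 Å, ∠C–X···A ≥ 120°), ionic (≤ 4.0 Å), metal
  complex (≤ 2.8 Å), aromatic atom pair (≤ 4.0 Å), hydrophobic (≤ 4.5 Å),
  carbonyl n→π* (≤ 3.6 Å), and the angle-free `polar` (≤ 3.5 Å) and
  `weak_polar` (≤ 4.0 Å) analogues that are robust to missing hydrogens.

Planar groups are handled at group level: aromatic rings (dictionary-defined
for standard residues, perceived as planar 5/6-cycles for ligands) and amide
groups give π–π stacking (centroids ≤ 6.0 Å, labelled
stacked/tilted/t-shaped by the folded interplanar angle), atom–ring
interactions over the ring face (cation–π, donor–π, halogen–π, carbon–π;
≤ 4.5 Å and ≤ 30° off the ring normal), amide–amide and amide–ring stacking,
and methionine sulphur–aromatic contacts (≤ 6.0 Å).

Contacts and group interactions are aggregated per residue into a binary
fingerprint and an integer fingerprint that counts *atoms* making each kind
of contact. All thresholds live in an editable YAML configuration.

## Worked example

An ideal water–water hydrogen bond (O···O 2.9 Å, linear O–H···O), generated
by the built-in fixture generator:

```r
library(pdbSIFt)
res <- calculateInteractions(makeFixture("hbond", "ideal"))
res
#> ContactResult: 2 contacts, 0 pi-pi, 0 atom-ring, 0 group interactions
#>   features: hbond=1, polar=1
contacts(res)[, c("atom_a", "atom_b", "distance", "distance_class", "hbond", "polar")]
#>   atom_a atom_b distance distance_class hbond polar
#> 1  A/1/O  B/1/O     2.90      vdw_clash  TRUE  TRUE
#> 2 A/1/H1  B/1/O     1.94      vdw_clash FALSE FALSE
```

The O···O pair overlaps the van der Waals radius sum (3.04 Å), so its
distance class is `vdw_clash`, and it carries both the geometric `hbond` bit
and its angle-free `polar` superset; the H···O pair is a plain distance-class
row. The per-residue fingerprints count atoms, not contacts:

```r
residueSIFts(res)[, c("chain_id", "res_name", "hbond_count", "vdw_clash_count")]
#>   chain_id res_name hbond_count vdw_clash_count
#> 1        A      HOH           1               2
#> 2        B      HOH           1               1
```

Two parallel benzene rings 3.8 Å apart are reported as a stacked π–π
interaction (`theta` is the interplanar angle in degrees):

```r
r <- calculateInteractions(makeFixture("pi_pi", "ideal"))
r@ringInteractions
#>   ring_a ring_b res_a res_b distance theta geometry
#> 1      1      2     1     2      3.8     0  stacked
```

From the shell, the same pipeline writes six TSV tables
(`.contacts.tsv`, `.rings.tsv`, `.atom_rings.tsv`, `.groups.tsv`,
`.residue_sifts.tsv`, `.summary.tsv`):

```sh
$ pdbsift complex.pdb -s "/B/1/" -o out/
1 contacts written
  proximal: 1
  ionic: 1
```

(The `pdbsift` script ships in `inst/scripts/`; `-s` takes
`/chain/resseq[icode]/atomname` selection items, repeatable, empty component
= wildcard. With a selection active, contacts are labelled `inter` when
exactly one endpoint is selected, and residue fingerprints are restricted to
those inter-entity contacts. `pdbsift fixtures --out DIR` dumps the full
fixture catalogue.)

## Scope

`pdbSIFt` reads fixed-column PDB (v3.3); mmCIF, structure repair, hydrogen
placement, pKa/tautomer prediction, energy scoring and water-network
analysis are out of scope. Multi-model files are never averaged: one model
is selected (default: the first). Alternate locations keep the
highest-occupancy conformer (ties broken alphabetically).
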