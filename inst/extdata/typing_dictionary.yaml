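# Physicochemical typing dictionary for standard polymer residues.
#
# Flags listed here are the residue-specific ones (donor/acceptor,
# ionisable, aromatic, carbonyl).  Context-dependent flags - hydrophobe,
# weak_donor, xbond_acceptor, halogen - are derived from the covalent
# connectivity by uniform rules at typing time, so an entry with [] still
# counts as "present in the dictionary" (every standard heavy atom must be).
#
# backbone maps are merged into every residue of the matching polymer class;
# per-residue entries override them (see overrides).

backbone:
  peptide:
    "N":   [hbond_donor]
    CA:  []
    C:   [carbonyl_carbon]
    O:   [hbond_acceptor, carbonyl_oxygen]
    OXT: [hbond_acceptor, neg_ionisable]
  nucleotide:
    P:    []
    OP1:  [hbond_acceptor, neg_ionisable]
    OP2:  [hbond_acceptor, neg_ionisable]
    OP3:  [hbond_acceptor, neg_ionisable]
    O1P:  [hbond_acceptor, neg_ionisable]
    O2P:  [hbond_acceptor, neg_ionisable]
    O3P:  [hbond_acceptor, neg_ionisable]
    O5':  [hbond_acceptor]
    C5':  []
    C4':  []
    O4':  [hbond_acceptor]
    C3':  []
    O3':  [hbond_acceptor]
    C2':  []
    O2':  [hbond_donor, hbond_acceptor]
    C1':  []

overrides:
  PRO:
    "N": []          # secondary amine: donor only when an H is modelled

residues:
  ALA: {CB: []}
  ARG:
    CB: []
    CG: []
    CD: []
    NE:  [hbond_donor, pos_ionisable]
    CZ:  [pos_ionisable]
    NH1: [hbond_donor, pos_ionisable]
    NH2: [hbond_donor, pos_ionisable]
  ASN:
    CB: []
    CG:  [carbonyl_carbon]
    OD1: [hbond_acceptor, carbonyl_oxygen]
    ND2: [hbond_donor]
  ASP:
    CB: []
    CG: []
    OD1: [hbond_acceptor, neg_ionisable]
    OD2: [hbond_acceptor, neg_ionisable]
  CYS:
    CB: []
    SG: [hbond_donor, hbond_acceptor]
  GLN:
    CB: []
    CG: []
    CD:  [carbonyl_carbon]
    OE1: [hbond_acceptor, carbonyl_oxygen]
    NE2: [hbond_donor]
  GLU:
    CB: []
    CG: []
    CD: []
    OE1: [hbond_acceptor, neg_ionisable]
    OE2: [hbond_acceptor, neg_ionisable]
  GLY: {}
  HIS:                  # ring-N donor/acceptor set by the leniency pass
    CB: []
    CG:  [aromatic]
    ND1: [aromatic]
    CD2: [aromatic]
    CE1: [aromatic]
    NE2: [aromatic]
  ILE: {CB: [], CG1: [], CG2: [], CD1: []}
  LEU: {CB: [], CG: [], CD1: [], CD2: []}
  LYS:
    CB: []
    CG: []
    CD: []
    CE: []
    NZ: [hbond_donor, pos_ionisable]
  MET:
    CB: []
    CG: []
    SD: [hbond_acceptor]
    CE: []
  PHE:
    CB: []
    CG:  [aromatic]
    CD1: [aromatic]
    CD2: [aromatic]
    CE1: [aromatic]
    CE2: [aromatic]
    CZ:  [aromatic]
  PRO: {CB: [], CG: [], CD: []}
  SER:
    CB: []
    OG: [hbond_donor, hbond_acceptor]
  THR:
    CB: []
    OG1: [hbond_donor, hbond_acceptor]
    CG2: []
  TRP:
    CB: []
    CG:  [aromatic]
    CD1: [aromatic]
    CD2: [aromatic]
    NE1: [hbond_donor, aromatic]
    CE2: [aromatic]
    CE3: [aromatic]
    CZ2: [aromatic]
    CZ3: [aromatic]
    CH2: [aromatic]
  TYR:
    CB: []
    CG:  [aromatic]
    CD1: [aromatic]
    CD2: [aromatic]
    CE1: [aromatic]
    CE2: [aromatic]
    CZ:  [aromatic]
    OH:  [hbond_donor, hbond_acceptor]
  VAL: {CB: [], CG1: [], CG2: []}
  HOH: {O: [hbond_donor, hbond_acceptor], OW: [hbond_donor, hbond_acceptor]}
  WAT: {O: [hbond_donor, hbond_acceptor]}
  DOD: {O: [hbond_donor, hbond_acceptor]}
  DA:
    N9: [aromatic]
    C8: [aromatic]
    N7: [hbond_acceptor, aromatic]
    C5: [aromatic]
    C6: [aromatic]
    N6: [hbond_donor]
    N1: [hbond_acceptor, aromatic]
    C2: [aromatic]
    N3: [hbond_acceptor, aromatic]
    C4: [aromatic]
  DG:
    N9: [aromatic]
    C8: [aromatic]
    N7: [hbond_acceptor, aromatic]
    C5: [aromatic]
    C6: [aromatic]
    O6: [hbond_acceptor]
    N1: [hbond_donor, aromatic]
    C2: [aromatic]
    N2: [hbond_donor]
    N3: [hbond_acceptor, aromatic]
    C4: [aromatic]
  DC:
    N1: [aromatic]
    C2: [aromatic]
    O2: [hbond_acceptor]
    N3: [hbond_acceptor, aromatic]
    C4: [aromatic]
    N4: [hbond_donor]
    C5: [aromatic]
    C6: [aromatic]
  DT:
    N1: [aromatic]
    C2: [aromatic]
    O2: [hbond_acceptor]
    N3: [hbond_donor, aromatic]
    C4: [aromatic]
    O4: [hbond_acceptor]
    C5: [aromatic]
    C7: []
    C5M: []
    C6: [aromatic]

# aromatic ring member lists (atom names, in ring order)
rings:
  PHE: [[CG, CD1, CE1, CZ, CE2, CD2]]
  TYR: [[CG, CD1, CE1, CZ, CE2, CD2]]
  TRP: [[CG, CD1, NE1, CE2, CD2], [CD2, CE2, CZ2, CH2, CZ3, CE3]]
  HIS: [[CG, ND1, CE1, NE2, CD2]]
  DA:  [[N9, C8, N7, C5, C4], [C4, C5, C6, N1, C2, N3]]
  DG:  [[N9, C8, N7, C5, C4], [C4, C5, C6, N1, C2, N3]]
  DC:  [[N1, C2, N3, C4, C5, C6]]
  DT:  [[N1, C2, N3, C4, C5, C6]]

# side-chain amide groups as [C, O, N]
amides:
  ASN: [[CG, OD1, ND2]]
  GLN: [[CD, OE1, NE2]]
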