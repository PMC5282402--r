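# Geometric thresholds for interatomic interaction detection.
# Distances in Angstroms, angles in degrees.  Every value can be overridden
# by pointing readGeometryConfig() (or the CLI -c flag) at an edited copy.
thresholds:
  cutoff: 5.0              # radial neighbour cutoff for contact enumeration
  cov_tol: 0.2             # half-width of the covalent-bond distance band
                           # (0.2 A so partial double bonds - e.g. the 1.33 A
                           # peptide C-N - fall inside the covalent class)
  vdw_comp: 0.1            # compensation added to vdW radius sums
  bond_tol: 0.45           # tolerance for covalent connectivity inference
  hbond_dist_max: 3.9      # donor...acceptor maximum
  hbond_h_dist_max: 2.7    # hydrogen...acceptor maximum (shared by weak H-bonds)
  hbond_angle_min: 90.0    # minimum D-H...A angle
  weak_hbond_dist_max: 3.6 # carbon-donor...acceptor maximum
  weak_hbond_angle_min: 130.0
  polar_dist_max: 3.5      # angle-free hydrogen-bond analogue
  weak_polar_dist_max: 4.0 # angle-free weak hydrogen-bond analogue
  xbond_angle_min: 120.0   # minimum C-X...A angle (sigma-hole directionality)
  ionic_dist_max: 4.0
  metal_dist_max: 2.8
  carbonyl_dist_max: 3.6   # carbonyl C...O (n->pi* dipole pairing)
  hydrophobic_dist_max: 4.5
  aromatic_dist_max: 4.0   # aromatic-atom to aromatic-atom
  ring_ring_dist_max: 6.0  # ring centroid to ring centroid (pi-pi)
  atom_ring_dist_max: 4.5  # atom to ring centroid
  atom_ring_angle_max: 30.0  # off-axis tolerance for "over the ring face"
  amide_amide_dist_max: 5.0
  amide_ring_dist_max: 4.5
  met_arom_dist_max: 6.0   # thioether sulphur to ring centroid
  planarity_tol: 0.1       # RMS out-of-plane maximum for hetero-ring acceptance
  pi_stack_angle_max: 30.0 # interplanar angle <= this: "stacked"
  pi_tshape_angle_min: 60.0  # interplanar angle >= this: "t_shaped"
options:
  water_names: [HOH, WAT, DOD]
  metal_elements: [LI, NA, K, RB, CS, MG, CA, SR, BA, MN, FE, CO, NI, CU, ZN, CD, HG]
  halogen_weak_acceptor: false   # treat C-bound halogens as weak H-bond acceptors
  sulphur_aromatic_residues: [MET]  # add CYS to include thiol S-aromatic contacts
# Covalent radii follow the Pyykko single-bond scale, van der Waals radii the
# Bondi scale (with common extensions for metals).  Angstroms.
radii:
  H:  {cov: 0.32, vdw: 1.20}
  C:  {cov: 0.75, vdw: 1.70}
  "N":  {cov: 0.71, vdw: 1.55}
  O:  {cov: 0.63, vdw: 1.52}
  F:  {cov: 0.64, vdw: 1.47}
  P:  {cov: 1.11, vdw: 1.80}
  S:  {cov: 1.03, vdw: 1.80}
  CL: {cov: 0.99, vdw: 1.75}
  BR: {cov: 1.14, vdw: 1.85}
  I:  {cov: 1.33, vdw: 1.98}
  B:  {cov: 0.85, vdw: 1.92}
  SE: {cov: 1.16, vdw: 1.90}
  LI: {cov: 1.33, vdw: 1.82}
  NA: {cov: 1.55, vdw: 2.27}
  K:  {cov: 1.96, vdw: 2.75}
  RB: {cov: 2.10, vdw: 3.03}
  CS: {cov: 2.32, vdw: 3.43}
  MG: {cov: 1.39, vdw: 1.73}
  CA: {cov: 1.71, vdw: 2.31}
  SR: {cov: 1.85, vdw: 2.49}
  BA: {cov: 1.96, vdw: 2.68}
  MN: {cov: 1.19, vdw: 2.05}
  FE: {cov: 1.16, vdw: 2.04}
  CO: {cov: 1.11, vdw: 2.00}
  NI: {cov: 1.10, vdw: 1.63}
  CU: {cov: 1.12, vdw: 1.40}
  ZN: {cov: 1.18, vdw: 1.39}
  CD: {cov: 1.36, vdw: 1.58}
  HG: {cov: 1.32, vdw: 1.55}
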