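# Independent oracles and hand-built fixtures shared across the suite.

# O(n^2) brute-force neighbour enumeration: the oracle the grid index is
# checked against.  Deliberately naive.
bruteForcePairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  ii <- integer(); jj <- integer(); dd <- numeric()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (d <= cutoff) {
          ii <- c(ii, i); jj <- c(jj, j); dd <- c(dd, d)
        }
      }
    }
  }
  data.frame(i = ii, j = jj, distance = dd)
}

# Random cloud of single-atom hetero residues as PDB text (each atom its own
# residue, so every pair is an inter-residue candidate).
randomStructureText <- function(n = 50, box = 12, seed = 1,
                                elements = c("C", "N", "O", "S")) {
  set.seed(seed)
  xyz <- matrix(runif(3 * n, 0, box), ncol = 3)
  el <- sample(elements, n, replace = TRUE)
  lines <- vapply(seq_len(n), function(k) {
    sprintf("HETATM%5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            k, paste0(el[k], 1), "UNL", "A", k,
            xyz[k, 1], xyz[k, 2], xyz[k, 3], 1, 0, el[k])
  }, "")
  list(text = paste(c(lines, "END"), collapse = "\n"), xyz = xyz,
       elements = el)
}

glyGlyText <- function() {
  paste(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.300   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.350   2.350   0.000  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       3.330   1.400   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       4.200   2.550   0.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       5.600   2.000   0.000  1.00  0.00           C",
    "ATOM      8  O   GLY A   2       6.000   0.900   0.300  1.00  0.00           O",
    "END", sep = "\n")
}

# Fixed-column ATOM/HETATM line builder for hand-made fixtures.
pdbLine <- function(serial, name, res, chain, seq, x, y, z, el,
                    het = FALSE, alt = " ", occ = 1) {
  nm <- if (nchar(el) >= 2 || nchar(name) >= 4) sprintf("%-4s", name)
        else sprintf(" %-3s", name)
  sprintf("%-6s%5d %s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, nm, alt, res, chain, seq,
          x, y, z, occ, 0, el)
}

pdbText <- function(...) paste(c(..., "END"), collapse = "\n")

# Chlorobenzene: benzene ring with Cl substituent on C1 (along +x).
chlorobenzeneText <- function() {
  ang <- (0:5) * pi / 3
  lines <- vapply(1:6, function(k) {
    pdbLine(k, paste0("C", k), "UNL", "A", 1, 1.39 * cos(ang[k]),
            1.39 * sin(ang[k]), 0, "C", het = TRUE)
  }, "")
  lines <- c(lines, pdbLine(7, "CL1", "UNL", "A", 1, 1.39 + 1.77, 0, 0, "CL",
                            het = TRUE))
  pdbText(lines)
}

# Histidine imidazole ring (regular pentagon, side 1.37 A) with an optional
# HD1 on ND1 and a carbonyl-bearing probe ligand placed near ND1.
hisRingText <- function(withHD1 = FALSE, probe = TRUE, probe_dist = 3.2) {
  ang <- pi / 2 + (0:4) * 2 * pi / 5
  r5 <- 1.37 / (2 * sin(pi / 5))
  nms <- c("CG", "ND1", "CE1", "NE2", "CD2")
  els <- c("C", "N", "C", "N", "C")
  lines <- vapply(1:5, function(k) {
    pdbLine(k, nms[k], "HIS", "A", 1, r5 * cos(ang[k]), r5 * sin(ang[k]), 0,
            els[k])
  }, "")
  nd1 <- c(r5 * cos(ang[2]), r5 * sin(ang[2]), 0)
  out_dir <- nd1 / sqrt(sum(nd1^2))
  k <- 5
  if (withHD1) {
    h <- nd1 + 1.01 * out_dir
    k <- k + 1
    lines <- c(lines, pdbLine(k, "HD1", "HIS", "A", 1, h[1], h[2], h[3], "H"))
  }
  if (probe) {
    # acceptor-only carbonyl oxygen pointed at ND1
    o <- nd1 + probe_dist * out_dir
    c_at <- o + 1.23 * out_dir
    lines <- c(lines,
               pdbLine(k + 1, "O1", "UNL", "B", 1, o[1], o[2], o[3], "O",
                       het = TRUE),
               pdbLine(k + 2, "C1", "UNL", "B", 1, c_at[1], c_at[2], c_at[3],
                       "C", het = TRUE))
  }
  pdbText(lines)
}

# Canonical heavy-atom names of the 20 standard amino acids (side chains),
# enumerated independently of the shipped dictionary.
AA_SIDECHAIN_ATOMS <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

# Rotation matrix about a unit axis by an angle (radians).
rotationMatrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  outer(u, u) * (1 - c_) + diag(3) * c_ +
    matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3) * s_
}

# Unordered contact signature for comparing runs: id pair + class + bits.
contactSignature <- function(cts) {
  key <- paste(pmin(cts$atom_a, cts$atom_b), pmax(cts$atom_a, cts$atom_b))
  bits <- apply(cts[, FEATURE_BITS], 1, paste, collapse = "")
  sort(paste(key, cts$distance_class, bits))
}
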