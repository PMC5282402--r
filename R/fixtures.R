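# Geometry-exact PDB fixture generation: minimal structures that place the
# defining geometric parameter of each interaction subtype at an ideal value
# or just inside/outside its threshold.  All coordinates are analytic;
# boundary variants are derived from the live GeometryConfig so threshold
# edits keep the suite self-consistent.

#' Fixture vocabulary
#'
#' The interaction subtypes the fixture generator supports: the five
#' distance classes, the ten atom-atom feature bits, the five ring
#' subtypes, and the three planar-group families.
#' @export
FIXTURE_SUBTYPES <- SIFT_TYPES

.BOUNDARY_DELTA <- 0.05  # Angstrom offset used for boundary variants

# ---------------------------------------------------------------------------
# PDB text assembly
# ---------------------------------------------------------------------------

.atomRow <- function(name, res_name, chain, res_seq, x, y, z, element,
                     het = TRUE) {
  data.frame(name = name, res_name = res_name, chain = chain,
             res_seq = res_seq, x = x, y = y, z = z, element = element,
             het = het, stringsAsFactors = FALSE)
}

.pdbAtomLine <- function(serial, name, res_name, chain, res_seq,
                         x, y, z, element, het) {
  nm <- if (nchar(element) >= 2 || nchar(name) >= 4) {
    sprintf("%-4s", name)
  } else {
    sprintf(" %-3s", name)
  }
  sprintf("%-6s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, nm, res_name, chain,
          res_seq, x, y, z, 1, 0, element)
}

.fixtureText <- function(atoms) {
  lines <- vapply(seq_len(nrow(atoms)), function(k) {
    .pdbAtomLine(k, atoms$name[k], atoms$res_name[k], atoms$chain[k],
                 atoms$res_seq[k], atoms$x[k], atoms$y[k], atoms$z[k],
                 atoms$element[k], atoms$het[k])
  }, "")
  paste(c(lines, "END"), collapse = "\n")
}

# Regular hexagonal carbon ring (side 1.39 A) in the z = z0 plane.
.benzene <- function(chain, res_seq, cx = 0, cy = 0, z0 = 0,
                     res_name = "BNZ") {
  ang <- (0:5) * pi / 3
  .atomRow(paste0("C", 1:6), res_name, chain, res_seq,
           cx + 1.39 * cos(ang), cy + 1.39 * sin(ang), rep(z0, 6), "C")
}

# Pyridine-like ring: N at angle `nangle` (radians), 5 carbons.
.pyridine <- function(chain, res_seq, cx, nangle) {
  ang <- nangle + (0:5) * pi / 3
  elements <- c("N", rep("C", 5))
  .atomRow(c("N1", paste0("C", 2:6)), "PYR", chain, res_seq,
           cx + 1.39 * cos(ang), 1.39 * sin(ang), rep(0, 6), elements)
}

# Planar formamide-like amide (C, O, N) in the z = 0 plane, centred so that
# the group centroid sits at the origin, then translated by (dx, dy, dz).
.formamide <- function(chain, res_seq, dx = 0, dy = 0, dz = 0) {
  pos <- rbind(C = c(0, 0, 0), O = c(1.23, 0, 0),
               N = 1.33 * c(cos(2 * pi / 3), sin(2 * pi / 3), 0))
  cen <- colMeans(pos)
  pos <- sweep(pos, 2, cen)
  .atomRow(c("C1", "O1", "N1"), "UNL", chain, res_seq,
           pos[, 1] + dx, pos[, 2] + dy, pos[, 3] + dz,
           c("C", "O", "N"))
}

# ---------------------------------------------------------------------------
# Per-subtype definitions: threshold accessor, ideal value, builder(d),
# and companion subtypes that legitimately co-occur in the ideal fixture.
# ---------------------------------------------------------------------------

.fixtureDefs <- function(config) {
  rO <- lookupRadii("O", config)
  rcovOO <- 2 * rO$cov
  rvdwOO <- 2 * rO$vdw
  tol <- .th(config, "cov_tol")
  comp <- .th(config, "vdw_comp")
  rClO <- lookupRadii(c("CL", "O"), config)

  twoOxygens <- function(d) {
    rbind(.atomRow("O1", "UNL", "A", 1, 0, 0, 0, "O"),
          .atomRow("O1", "UNL", "B", 1, d, 0, 0, "O"))
  }

  list(
    clash = list(
      threshold = rcovOO - tol, ideal = rcovOO - tol - 0.16,
      companions = character(), build = twoOxygens),
    covalent = list(
      threshold = rcovOO + tol, ideal = rcovOO,
      companions = character(), build = twoOxygens),
    vdw_clash = list(
      threshold = rvdwOO, ideal = (rcovOO + tol + rvdwOO) / 2,
      companions = character(), build = twoOxygens),
    vdw = list(
      threshold = rvdwOO + comp, ideal = rvdwOO + comp / 2,
      companions = character(), build = twoOxygens),
    proximal = list(
      threshold = .th(config, "cutoff"), ideal = 4.5,
      companions = character(), build = twoOxygens),
    hbond = list(  # parameter: H...acceptor distance, linear O-H...O
      threshold = .th(config, "hbond_h_dist_max"), ideal = 1.94,
      companions = "polar",
      build = function(d) rbind(
        .atomRow(c("O", "H1"), "HOH", "A", 1, c(0, 0.96), c(0, 0), c(0, 0),
                 c("O", "H")),
        .atomRow("O", "HOH", "B", 1, 0.96 + d, 0, 0, "O"))),
    weak_hbond = list(  # parameter: C...acceptor distance, linear C-H...O
      threshold = .th(config, "weak_hbond_dist_max"), ideal = 3.3,
      companions = "weak_polar",
      build = function(d) rbind(
        .atomRow(c("C1", "H1"), "UNL", "A", 1, c(0, 1.09), c(0, 0), c(0, 0),
                 c("C", "H")),
        .atomRow("O", "HOH", "B", 1, d, 0, 0, "O"))),
    xbond = list(  # parameter: Cl...O distance, linear C-Cl...O
      threshold = sum(rClO$vdw) + comp, ideal = 3.1,
      companions = character(),
      build = function(d) rbind(
        .atomRow(c("C1", "CL1"), "UNL", "A", 1, c(0, 1.77), c(0, 0), c(0, 0),
                 c("C", "CL")),
        .atomRow("O", "HOH", "B", 1, 1.77 + d, 0, 0, "O"))),
    ionic = list(
      threshold = .th(config, "ionic_dist_max"), ideal = 3.7,
      companions = character(),
      build = function(d) rbind(
        .atomRow("NZ", "LYS", "A", 1, 0, 0, 0, "N", het = FALSE),
        .atomRow("OD1", "ASP", "B", 1, d, 0, 0, "O", het = FALSE))),
    metal = list(
      threshold = .th(config, "metal_dist_max"), ideal = 2.1,
      companions = character(),
      build = function(d) rbind(
        .atomRow("ZN", "ZN", "A", 1, 0, 0, 0, "ZN"),
        .atomRow("O", "HOH", "B", 1, d, 0, 0, "O"))),
    aromatic = list(  # parameter: closest N...N gap of coplanar pyridines
      threshold = .th(config, "aromatic_dist_max"), ideal = 3.7,
      companions = character(),
      build = function(d) rbind(
        .pyridine("A", 1, 0, 0),
        .pyridine("B", 1, 2 * 1.39 + d, pi))),
    hydrophobic = list(
      threshold = .th(config, "hydrophobic_dist_max"), ideal = 4.2,
      companions = character(),
      build = function(d) rbind(
        .atomRow("CD1", "LEU", "A", 1, 0, 0, 0, "C", het = FALSE),
        .atomRow("CD1", "LEU", "B", 1, d, 0, 0, "C", het = FALSE))),
    carbonyl = list(  # parameter: O...C distance of antiparallel C=O pair
      threshold = .th(config, "carbonyl_dist_max"), ideal = 3.2,
      companions = character(),
      build = function(d) rbind(
        .atomRow(c("C1", "O1"), "UNL", "A", 1, c(0, 1.23), c(0, 0), c(0, 0),
                 c("C", "O")),
        .atomRow(c("C1", "O1"), "UNL", "B", 1, c(1.23, 0), c(d, d), c(0, 0),
                 c("C", "O")))),
    polar = list(
      threshold = .th(config, "polar_dist_max"), ideal = 3.2,
      companions = character(),
      build = function(d) rbind(
        .atomRow("OG", "SER", "A", 1, 0, 0, 0, "O", het = FALSE),
        .atomRow("O", "HOH", "B", 1, d, 0, 0, "O"))),
    weak_polar = list(
      threshold = .th(config, "weak_polar_dist_max"), ideal = 3.8,
      companions = character(),
      build = function(d) rbind(
        .atomRow("CD1", "LEU", "A", 1, 0, 0, 0, "C", het = FALSE),
        .atomRow("O", "HOH", "B", 1, d, 0, 0, "O"))),
    pi_pi = list(  # parameter: centroid-centroid distance, parallel stack
      threshold = .th(config, "ring_ring_dist_max"), ideal = 3.8,
      companions = c("aromatic", "hydrophobic", "carbon_pi"),
      build = function(d) rbind(
        .benzene("A", 1), .benzene("B", 1, z0 = d))),
    cation_pi = list(  # parameter: on-axis centroid distance
      threshold = .th(config, "atom_ring_dist_max"), ideal = 3.5,
      companions = "donor_pi",
      build = function(d) rbind(
        .benzene("A", 1),
        .atomRow("NZ", "LYS", "B", 1, 0, 0, d, "N", het = FALSE))),
    donor_pi = list(
      threshold = .th(config, "atom_ring_dist_max"), ideal = 3.5,
      companions = "weak_polar",
      build = function(d) rbind(
        .benzene("A", 1),
        .atomRow("OG", "SER", "B", 1, 0, 0, d, "O", het = FALSE))),
    halogen_pi = list(
      threshold = .th(config, "atom_ring_dist_max"), ideal = 3.5,
      companions = "hydrophobic",
      build = function(d) rbind(
        .benzene("A", 1),
        .atomRow(c("CL1", "C1"), "UNL", "B", 1, c(0, 0), c(0, 0),
                 c(d, d + 1.77), c("CL", "C")))),
    carbon_pi = list(
      threshold = .th(config, "atom_ring_dist_max"), ideal = 3.8,
      companions = "hydrophobic",
      build = function(d) rbind(
        .benzene("A", 1),
        .atomRow("CD1", "LEU", "B", 1, 0, 0, d, "C", het = FALSE))),
    amide_amide = list(  # parameter: centroid distance of stacked amides
      # 3.45 keeps every atom pair strictly inside one distance class
      # (3.5 would put the C...C pair exactly on the vdW band edge)
      threshold = .th(config, "amide_amide_dist_max"), ideal = 3.45,
      companions = character(),
      build = function(d) rbind(
        .formamide("A", 1), .formamide("B", 1, dz = d))),
    amide_ring = list(
      threshold = .th(config, "amide_ring_dist_max"), ideal = 3.8,
      companions = c("donor_pi", "weak_polar"),
      build = function(d) rbind(
        .benzene("A", 1), .formamide("B", 1, dz = d))),
    met_aromatic = list(
      threshold = .th(config, "met_arom_dist_max"), ideal = 5.0,
      companions = character(),
      build = function(d) rbind(
        .benzene("A", 1),
        .atomRow("SD", "MET", "B", 1, 0, 0, d, "S", het = FALSE)))
  )
}

#' Generate a minimal PDB fixture for one interaction subtype
#'
#' The defining geometric parameter (a distance) is placed at an ideal value
#' well inside the thresholds, just inside the threshold
#' (\code{boundary_pass}: threshold - 0.05 A), or just outside
#' (\code{boundary_fail}: threshold + 0.05 A).  Atom naming is chosen so
#' typing is dictionary-driven where possible.
#'
#' @param subtype one of \code{\link{FIXTURE_SUBTYPES}}.
#' @param variant "ideal", "boundary_pass" or "boundary_fail".
#' @param config a \code{\link{GeometryConfig-class}} the boundaries are
#'   derived from.
#' @return PDB text (single string).
#' @examples
#' cat(makeFixture("ionic", "ideal"))
#' @export
makeFixture <- function(subtype, variant = c("ideal", "boundary_pass",
                                             "boundary_fail"),
                        config = NULL) {
  variant <- match.arg(variant)
  config <- .asConfig(config)
  defs <- .fixtureDefs(config)
  if (!subtype %in% names(defs)) {
    stop("unknown fixture subtype '", subtype, "'; supported: ",
         paste(names(defs), collapse = ", "))
  }
  def <- defs[[subtype]]
  d <- switch(variant,
              ideal = def$ideal,
              boundary_pass = def$threshold - .BOUNDARY_DELTA,
              boundary_fail = def$threshold + .BOUNDARY_DELTA)
  .fixtureText(def$build(d))
}

#' Full fixture catalogue
#'
#' The cross product of every supported subtype with the three variants,
#' annotated with the expected detection outcome and the companion subtypes
#' that legitimately co-occur with the intended one.
#'
#' @param config a \code{\link{GeometryConfig-class}}.
#' @return data.frame: subtype, variant, expected (logical: should the
#'   intended subtype be detected), pdb (text), and a \code{companions}
#'   list column.
#' @export
fixtureCatalogue <- function(config = NULL) {
  config <- .asConfig(config)
  defs <- .fixtureDefs(config)
  grid <- expand.grid(subtype = names(defs),
                      variant = c("ideal", "boundary_pass", "boundary_fail"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$subtype, names(defs))), ]
  rownames(grid) <- NULL
  grid$expected <- grid$variant != "boundary_fail"
  grid$pdb <- vapply(seq_len(nrow(grid)), function(k) {
    makeFixture(grid$subtype[k], grid$variant[k], config)
  }, "")
  grid$companions <- I(lapply(grid$subtype, function(s) defs[[s]]$companions))
  grid
}

#' Which subtypes does a result contain?
#'
#' @param result a \code{\link{ContactResult-class}}.
#' @return named logical vector over \code{\link{FIXTURE_SUBTYPES}}.
#' @export
detectedSubtypes <- function(result) {
  out <- stats::setNames(logical(length(SIFT_TYPES)), SIFT_TYPES)
  cc <- result@contacts
  for (t in DISTANCE_CLASSES) out[t] <- any(cc$distance_class == t)
  for (t in FEATURE_BITS) out[t] <- any(cc[[t]])
  out["pi_pi"] <- nrow(result@ringInteractions) > 0
  ar <- result@atomRingInteractions
  if (nrow(ar)) {
    for (t in c("cation_pi", "donor_pi", "halogen_pi", "carbon_pi")) {
      out[t] <- any(ar[[t]])
    }
  }
  gr <- result@groupInteractions
  if (nrow(gr)) {
    out["amide_amide"] <- any(gr$kind == "amide_amide")
    out["amide_ring"] <- any(gr$kind == "amide_ring")
  }
  out["met_aromatic"] <- nrow(result@metInteractions) > 0
  out
}

#' Write the fixture catalogue to disk
#'
#' Dumps every catalogue entry as \code{<subtype>_<variant>.pdb} plus a
#' \code{manifest.tsv} with the expected outcomes (the CLI
#' \code{fixtures --out DIR} subcommand).
#'
#' @param dir output directory (created if needed).
#' @param config a \code{\link{GeometryConfig-class}}.
#' @return the manifest data.frame, invisibly.
#' @export
writeFixtureCatalogue <- function(dir, config = NULL) {
  cat_df <- fixtureCatalogue(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cat_df$file <- paste0(cat_df$subtype, "_", cat_df$variant, ".pdb")
  for (k in seq_len(nrow(cat_df))) {
    writeLines(cat_df$pdb[k], file.path(dir, cat_df$file[k]))
  }
  manifest <- data.frame(subtype = cat_df$subtype, variant = cat_df$variant,
                         file = cat_df$file,
                         expected = as.integer(cat_df$expected),
                         stringsAsFactors = FALSE)
  .writeTSV(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Apply an exact rigid-body motion to a parsed structure
#'
#' Transforms the coordinates in place (full double precision, unlike
#' \code{\link{transformPDB}} which round-trips through 3-decimal PDB text).
#' Bond inference and typing are distance-based, so both are preserved by a
#' rigid motion.
#'
#' @param structure a \code{\link{PDBStructure-class}}.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector.
#' @return the transformed structure.
#' @export
transformStructure <- function(structure, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  xyz <- .xyz(structure) %*% t(rotation)
  structure@atoms$x <- xyz[, 1] + translation[1]
  structure@atoms$y <- xyz[, 2] + translation[2]
  structure@atoms$z <- xyz[, 3] + translation[3]
  structure
}

#' Apply a rigid-body motion to PDB text
#'
#' Rotates and translates every ATOM/HETATM coordinate; all other columns
#' are untouched.  Useful for testing that detection is invariant under
#' rigid motion.
#'
#' @param pdb PDB text or a path.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector.
#' @return transformed PDB text (single string).
#' @export
transformPDB <- function(pdb, rotation = diag(3), translation = c(0, 0, 0)) {
  lines <- .pdbLines(pdb)
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  for (k in which(isAtom)) {
    xyz <- as.numeric(c(substr(lines[k], 31, 38), substr(lines[k], 39, 46),
                        substr(lines[k], 47, 54)))
    new <- as.numeric(rotation %*% xyz + translation)
    substr(lines[k], 31, 54) <- sprintf("%8.3f%8.3f%8.3f",
                                        new[1], new[2], new[3])
  }
  paste(lines, collapse = "\n")
}
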