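# Group-level interactions: ring-ring (pi-pi), atom-ring (cation/donor/
# halogen/carbon-pi), amide-amide, amide-ring, and thioether S-aromatic.

.centroids <- function(df) cbind(df$cx, df$cy, df$cz)
.normals <- function(df) cbind(df$nx, df$ny, df$nz)

#' Ring-ring (pi-pi) interactions
#'
#' A pi-pi interaction is recorded for every pair of distinct,
#' non-atom-sharing rings whose centroids lie within ring_ring_dist_max.
#' The interplanar angle theta (angle between normals folded to [0, 90]
#' degrees) gives the geometry label: stacked (theta <= 30), tilted, or
#' t_shaped (theta >= 60).
#'
#' @param rings ring table from \code{\link{perceiveRings}}.
#' @param config a \code{\link{GeometryConfig-class}}.
#' @return data.frame: ring_a, ring_b, res_a, res_b, distance, theta,
#'   geometry.  Each unordered pair appears once.
#' @export
ringRingInteractions <- function(rings, config = NULL) {
  config <- .asConfig(config)
  out <- data.frame(ring_a = integer(), ring_b = integer(),
                    res_a = integer(), res_b = integer(),
                    distance = numeric(), theta = numeric(),
                    geometry = character(), stringsAsFactors = FALSE)
  if (nrow(rings) < 2) return(out)
  cen <- .centroids(rings); nor <- .normals(rings)
  dmax <- .th(config, "ring_ring_dist_max")
  for (p in seq_len(nrow(rings) - 1)) {
    for (q in seq((p + 1), nrow(rings))) {
      if (length(intersect(rings$members[[p]], rings$members[[q]]))) next
      dd <- .dist3(cen[p, ], cen[q, ])
      if (dd > dmax) next
      theta <- .foldAngle(.angleDeg(nor[p, ], nor[q, ]))
      out[nrow(out) + 1L, ] <- list(
        rings$ring_id[p], rings$ring_id[q],
        rings$res_index[p], rings$res_index[q],
        dd, theta, .piGeometryLabel(theta, config))
    }
  }
  out
}

.piGeometryLabel <- function(theta, config) {
  if (theta <= .th(config, "pi_stack_angle_max")) "stacked"
  else if (theta >= .th(config, "pi_tshape_angle_min")) "t_shaped"
  else "tilted"
}

#' Atom-ring interactions (cation-pi, donor-pi, halogen-pi, carbon-pi)
#'
#' An atom interacts with a ring face when its distance to the ring centroid
#' is within atom_ring_dist_max and the angle between the ring normal and
#' the centroid-to-atom vector is within atom_ring_angle_max.  Subtypes
#' follow the atom's flags and are not mutually exclusive: pos_ionisable ->
#' cation_pi, hbond_donor -> donor_pi, xbond_donor -> halogen_pi, weak-donor
#' carbon -> carbon_pi.  Ring members and atoms of the ring's own parent
#' residue(s) are excluded.
#'
#' @param structure a typed \code{\link{PDBStructure-class}}.
#' @param rings ring table from \code{\link{perceiveRings}}.
#' @param config a \code{\link{GeometryConfig-class}}.
#' @return data.frame: atom, atom_id, ring_id, res_atom, res_ring, distance,
#'   theta, and logical columns cation_pi, donor_pi, halogen_pi, carbon_pi.
#' @export
atomRingInteractions <- function(structure, rings, config = NULL) {
  config <- .asConfig(config)
  if (!structure@typed) stop("structure must be typed first")
  a <- structure@atoms
  fl <- structure@flags
  xyz <- .xyz(structure)
  out <- data.frame(atom = integer(), atom_id = character(),
                    ring_id = integer(), res_atom = integer(),
                    res_ring = integer(), distance = numeric(),
                    theta = numeric(), cation_pi = logical(),
                    donor_pi = logical(), halogen_pi = logical(),
                    carbon_pi = logical(), stringsAsFactors = FALSE)
  if (!nrow(rings)) return(out)
  carbon_weak <- fl[, "weak_donor"] & a$element == "C"
  cand <- which((fl[, "pos_ionisable"] | fl[, "hbond_donor"] |
                 fl[, "xbond_donor"] | carbon_weak) & !fl[, "metal"])
  if (!length(cand)) return(out)
  dmax <- .th(config, "atom_ring_dist_max")
  amax <- .th(config, "atom_ring_angle_max")
  cen <- .centroids(rings); nor <- .normals(rings)
  for (q in seq_len(nrow(rings))) {
    members <- rings$members[[q]]
    ring_res <- unique(a$res_index[members])
    for (i in cand) {
      if (i %in% members || a$res_index[i] %in% ring_res) next
      v <- xyz[i, ] - cen[q, ]
      dd <- .vnorm(v)
      if (dd > dmax) next
      theta <- .foldAngle(.angleDeg(nor[q, ], v))
      if (theta > amax) next
      out[nrow(out) + 1L, ] <- list(
        i, .atomIds(a, i), rings$ring_id[q], a$res_index[i],
        rings$res_index[q], dd, theta,
        fl[i, "pos_ionisable"], fl[i, "hbond_donor"],
        fl[i, "xbond_donor"], carbon_weak[i])
    }
  }
  out
}

#' Amide-amide and amide-ring group interactions
#'
#' Two amide groups interact when their centroids are within
#' amide_amide_dist_max; an amide and an aromatic ring within
#' amide_ring_dist_max.  The interplanar angle is reported.  Pairs sharing
#' an atom or a parent residue are skipped.
#'
#' @param amides amide table from \code{\link{perceiveAmides}}.
#' @param rings ring table from \code{\link{perceiveRings}}.
#' @param config a \code{\link{GeometryConfig-class}}.
#' @return data.frame: kind (amide_amide / amide_ring), group_a, group_b
#'   (amide group_id; ring_id for amide_ring), distance, theta.
#' @export
amideGroupInteractions <- function(amides, rings, config = NULL) {
  config <- .asConfig(config)
  out <- data.frame(kind = character(), group_a = integer(),
                    group_b = integer(), distance = numeric(),
                    theta = numeric(), stringsAsFactors = FALSE)
  na <- nrow(amides)
  if (na >= 2) {
    cen <- .centroids(amides); nor <- .normals(amides)
    dmax <- .th(config, "amide_amide_dist_max")
    for (p in seq_len(na - 1)) {
      for (q in seq(p + 1, na)) {
        if (length(intersect(amides$members[[p]], amides$members[[q]]))) next
        dd <- .dist3(cen[p, ], cen[q, ])
        if (dd > dmax) next
        out[nrow(out) + 1L, ] <- list(
          "amide_amide", amides$group_id[p], amides$group_id[q], dd,
          .foldAngle(.angleDeg(nor[p, ], nor[q, ])))
      }
    }
  }
  if (na >= 1 && nrow(rings)) {
    cenA <- .centroids(amides); norA <- .normals(amides)
    cenR <- .centroids(rings); norR <- .normals(rings)
    dmax <- .th(config, "amide_ring_dist_max")
    for (p in seq_len(na)) {
      for (q in seq_len(nrow(rings))) {
        if (length(intersect(amides$members[[p]], rings$members[[q]]))) next
        if (rings$res_index[q] %in% amides$parents[[p]]) next
        dd <- .dist3(cenA[p, ], cenR[q, ])
        if (dd > dmax) next
        out[nrow(out) + 1L, ] <- list(
          "amide_ring", amides$group_id[p], rings$ring_id[q], dd,
          .foldAngle(.angleDeg(norA[p, ], norR[q, ])))
      }
    }
  }
  out
}

#' Methionine sulphur-aromatic interactions
#'
#' Records thioether sulphur atoms (Met SD by default; Cys SG when
#' configured) within met_arom_dist_max of an aromatic ring centroid,
#' with the sulphur's elevation angle above the ring plane.
#'
#' @param structure a typed \code{\link{PDBStructure-class}}.
#' @param rings ring table from \code{\link{perceiveRings}}.
#' @param config a \code{\link{GeometryConfig-class}}; its
#'   \code{sulphur_aromatic_residues} option names the residues considered.
#' @return data.frame: atom, atom_id, ring_id, res_atom, res_ring, distance,
#'   elevation (degrees above the ring plane).
#' @export
metSulphurAromatic <- function(structure, rings, config = NULL) {
  config <- .asConfig(config)
  a <- structure@atoms
  xyz <- .xyz(structure)
  out <- data.frame(atom = integer(), atom_id = character(),
                    ring_id = integer(), res_atom = integer(),
                    res_ring = integer(), distance = numeric(),
                    elevation = numeric(), stringsAsFactors = FALSE)
  if (!nrow(rings)) return(out)
  resset <- config@options$sulphur_aromatic_residues
  s_atoms <- which((a$res_name == "MET" & a$name == "SD" & "MET" %in% resset) |
                   (a$res_name == "CYS" & a$name == "SG" & "CYS" %in% resset))
  if (!length(s_atoms)) return(out)
  dmax <- .th(config, "met_arom_dist_max")
  cen <- .centroids(rings); nor <- .normals(rings)
  for (q in seq_len(nrow(rings))) {
    ring_res <- unique(a$res_index[rings$members[[q]]])
    for (i in s_atoms) {
      if (a$res_index[i] %in% ring_res) next
      v <- xyz[i, ] - cen[q, ]
      dd <- .vnorm(v)
      if (dd > dmax) next
      elevation <- 90 - .foldAngle(.angleDeg(nor[q, ], v))
      out[nrow(out) + 1L, ] <- list(
        i, .atomIds(a, i), rings$ring_id[q], a$res_index[i],
        rings$res_index[q], dd, elevation)
    }
  }
  out
}
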