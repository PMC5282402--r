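# Contact enumeration and classification: grid-based neighbour search,
# mutually exclusive distance classes, and per-pair feature interaction bits.

# Grid (cell-list) spatial index: all unordered pairs with d <= cutoff.
# Atoms are binned into cubic cells of edge `cutoff`; each pair is examined
# once via the 13 lexicographically positive cell offsets plus the home cell.
.gridPairs <- function(xyz, cutoff) {
  empty <- data.frame(i = integer(), j = integer(), distance = numeric())
  n <- nrow(xyz)
  if (is.null(n) || n < 2) return(empty)
  origin <- apply(xyz, 2, min)
  cell <- floor(sweep(xyz, 2, origin) / cutoff)
  storage.mode(cell) <- "integer"
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(n), key)
  bcell <- do.call(rbind, lapply(strsplit(names(buckets), " ", fixed = TRUE),
                                 as.integer))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 1] > 0 |
               (offs[, 1] == 0 & (offs[, 2] > 0 |
                                  (offs[, 2] == 0 & offs[, 3] > 0))), ,
               drop = FALSE]
  ii <- list(); jj <- list(); k <- 0L
  for (b in seq_along(buckets)) {
    A <- buckets[[b]]
    if (length(A) > 1) {
      cmb <- utils::combn(A, 2)
      k <- k + 1L; ii[[k]] <- cmb[1, ]; jj[[k]] <- cmb[2, ]
    }
    for (o in seq_len(nrow(offs))) {
      nb <- paste(bcell[b, 1] + offs[o, 1], bcell[b, 2] + offs[o, 2],
                  bcell[b, 3] + offs[o, 3])
      B <- buckets[[nb]]
      if (!is.null(B)) {
        k <- k + 1L
        ii[[k]] <- rep(A, times = length(B))
        jj[[k]] <- rep(B, each = length(A))
      }
    }
  }
  if (k == 0L) return(empty)
  i <- unlist(ii); j <- unlist(jj)
  d2 <- (xyz[i, 1] - xyz[j, 1])^2 + (xyz[i, 2] - xyz[j, 2])^2 +
    (xyz[i, 3] - xyz[j, 3])^2
  keep <- d2 <= cutoff^2
  i <- i[keep]; j <- j[keep]
  d <- sqrt(d2[keep])
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  ord <- order(i, j)
  data.frame(i = i[ord], j = j[ord], distance = d[ord])
}

#' Enumerate neighbouring atom pairs
#'
#' All unordered atom pairs (heavy and hydrogen) within the radial cutoff,
#' each exactly once, found with a grid spatial index.  Intra-residue pairs
#' are included here (they feed bond inference) and are excluded later at
#' contact-building time.
#'
#' @param x a \code{\link{PDBStructure-class}} or an n x 3 coordinate matrix.
#' @param cutoff radial cutoff in Angstroms (default: the configured 5.0).
#' @param config a \code{\link{GeometryConfig-class}} (used when
#'   \code{cutoff} is missing).
#' @return data.frame with columns \code{i}, \code{j} (row indices, i < j)
#'   and \code{distance}.
#' @export
neighborPairs <- function(x, cutoff = NULL, config = NULL) {
  config <- .asConfig(config)
  if (is.null(cutoff)) cutoff <- .th(config, "cutoff")
  xyz <- if (is(x, "PDBStructure")) .xyz(x) else as.matrix(x)
  .gridPairs(xyz, cutoff)
}

#' Classify an interatomic distance
#'
#' With Rcov the covalent-radius sum and Rvdw the van der Waals sum:
#' \code{clash} if d < Rcov - cov_tol; \code{covalent} within cov_tol of
#' Rcov; \code{vdw_clash} below Rvdw; \code{vdw} up to Rvdw + vdw_comp;
#' \code{proximal} otherwise.  Exactly one class is returned per pair.
#'
#' @param distance numeric vector of distances (Angstrom).
#' @param element_a,element_b element symbols (recycled).
#' @param config a \code{\link{GeometryConfig-class}}.
#' @param strict error (rather than fall back to carbon radii) on unknown
#'   elements.
#' @return character vector drawn from \code{\link{DISTANCE_CLASSES}}.
#' @export
classifyDistance <- function(distance, element_a, element_b, config = NULL,
                             strict = TRUE) {
  config <- .asConfig(config)
  ra <- lookupRadii(element_a, config, strict = strict)
  rb <- lookupRadii(element_b, config, strict = strict)
  rcov <- ra$cov + rb$cov
  rvdw <- ra$vdw + rb$vdw
  tol <- .th(config, "cov_tol")
  comp <- .th(config, "vdw_comp")
  ifelse(distance < rcov - tol, "clash",
    ifelse(distance <= rcov + tol, "covalent",
      ifelse(distance < rvdw, "vdw_clash",
        ifelse(distance <= rvdw + comp, "vdw", "proximal"))))
}

# ---------------------------------------------------------------------------
# Geometric detectors (pure geometry; flag gating happens in buildContacts)
# ---------------------------------------------------------------------------

#' Hydrogen-bond geometry test
#'
#' TRUE iff donor...acceptor <= hbond_dist_max, some donor hydrogen has
#' H...acceptor <= hbond_h_dist_max, and the D-H...A angle at the hydrogen
#' is >= hbond_angle_min.  With no hydrogens the test is FALSE (the
#' angle-free polar contact covers that case).
#'
#' @param donor,acceptor numeric xyz coordinates.
#' @param hydrogens matrix of hydrogen coordinates (rows), or NULL.
#' @param config a \code{\link{GeometryConfig-class}}.
#' @export
detectHbond <- function(donor, hydrogens, acceptor, config = NULL) {
  config <- .asConfig(config)
  .hbondGeometry(donor, hydrogens, acceptor,
                 .th(config, "hbond_dist_max"),
                 .th(config, "hbond_h_dist_max"),
                 .th(config, "hbond_angle_min"))
}

#' Weak (carbon-donor) hydrogen-bond geometry test
#'
#' As \code{\link{detectHbond}} with the weak thresholds (C-H donors).
#' @inheritParams detectHbond
#' @export
detectWeakHbond <- function(donor, hydrogens, acceptor, config = NULL) {
  config <- .asConfig(config)
  .hbondGeometry(donor, hydrogens, acceptor,
                 .th(config, "weak_hbond_dist_max"),
                 .th(config, "hbond_h_dist_max"),
                 .th(config, "weak_hbond_angle_min"))
}

.hbondGeometry <- function(donor, hydrogens, acceptor, dmax, hmax, amin) {
  if (.dist3(donor, acceptor) > dmax) return(FALSE)
  if (is.null(hydrogens) || nrow(as.matrix(hydrogens)) == 0) return(FALSE)
  hmat <- matrix(as.matrix(hydrogens), ncol = 3)
  for (r in seq_len(nrow(hmat))) {
    h <- hmat[r, ]
    if (.dist3(h, acceptor) <= hmax &&
        .angleDeg(donor - h, acceptor - h) >= amin) {
      return(TRUE)
    }
  }
  FALSE
}

#' Polar (angle-free hydrogen-bond analogue) test
#'
#' Distance-only: TRUE iff donor...acceptor <= polar_dist_max.  Robust to
#' missing hydrogens.
#' @inheritParams detectHbond
#' @export
detectPolar <- function(donor, acceptor, config = NULL) {
  config <- .asConfig(config)
  .dist3(donor, acceptor) <= .th(config, "polar_dist_max")
}

#' Weak-polar (angle-free weak hydrogen-bond analogue) test
#' @inheritParams detectHbond
#' @export
detectWeakPolar <- function(donor, acceptor, config = NULL) {
  config <- .asConfig(config)
  .dist3(donor, acceptor) <= .th(config, "weak_polar_dist_max")
}

#' Halogen-bond geometry test
#'
#' TRUE iff X...A <= rvdw(X) + rvdw(A) + vdw_comp and the C-X...A angle is
#' >= xbond_angle_min (sigma-hole directionality).
#'
#' @param halogen,carbon,acceptor numeric xyz coordinates (carbon = the
#'   halogen's bound carbon).
#' @param halogen_element,acceptor_element element symbols for the radius
#'   lookup.
#' @param config a \code{\link{GeometryConfig-class}}.
#' @export
detectXbond <- function(halogen, carbon, acceptor, config = NULL,
                        halogen_element = "CL", acceptor_element = "O") {
  config <- .asConfig(config)
  r <- lookupRadii(c(halogen_element, acceptor_element), config)
  dmax <- sum(r$vdw) + .th(config, "vdw_comp")
  .dist3(halogen, acceptor) <= dmax &&
    .angleDeg(carbon - halogen, acceptor - halogen) >=
      .th(config, "xbond_angle_min")
}

# ---------------------------------------------------------------------------
# Contact assembly
# ---------------------------------------------------------------------------

#' Build classified contacts for a typed structure
#'
#' Enumerates inter-residue atom pairs within the cutoff, assigns each its
#' distance class and feature bits, suppresses feature bits on clash or
#' covalent contacts and on 1-2/1-3 bonded cross-residue pairs, and labels
#' each contact by its relation to the active selection.
#'
#' @param structure a typed \code{\link{PDBStructure-class}}.
#' @param config a \code{\link{GeometryConfig-class}} (NULL = default).
#' @param selectionAtoms integer atom indices of the active selection, or
#'   NULL for no selection.
#' @return data.frame: i, j (atom row indices, ordered by serial), atom_a,
#'   atom_b (chain/resseq[icode]/name identifiers), distance,
#'   distance_class, one logical column per \code{\link{FEATURE_BITS}},
#'   entity label.
#' @export
buildContacts <- function(structure, config = NULL, selectionAtoms = NULL) {
  config <- .asConfig(config)
  if (!structure@typed) stop("structure must be typed (assignAtomTypes) first")
  a <- structure@atoms
  fl <- structure@flags
  xyz <- .xyz(structure)
  pairs <- .gridPairs(xyz, .th(config, "cutoff"))
  pairs <- pairs[a$res_index[pairs$i] != a$res_index[pairs$j], , drop = FALSE]
  n <- nrow(pairs)
  feat <- matrix(FALSE, n, length(FEATURE_BITS),
                 dimnames = list(NULL, FEATURE_BITS))
  if (n == 0) {
    return(.contactsDf(structure, pairs, character(), feat, character()))
  }
  i <- pairs$i; j <- pairs$j; d <- pairs$distance

  cls <- classifyDistance(d, a$element[i], a$element[j], config,
                          strict = FALSE)

  adj <- .adjacency(structure)
  bkey <- if (nrow(structure@bonds)) {
    paste(pmin(structure@bonds[, 1], structure@bonds[, 2]),
          pmax(structure@bonds[, 1], structure@bonds[, 2]))
  } else character()
  direct <- paste(i, j) %in% bkey
  one_three <- mapply(function(x, y) length(intersect(adj[[x]], adj[[y]])) > 0,
                      i, j)
  suppressed <- direct | one_three | cls %in% c("clash", "covalent")

  don <- fl[, "hbond_donor"]; acc <- fl[, "hbond_acceptor"]
  wdon <- fl[, "weak_donor"]; wacc <- fl[, "weak_acceptor"]
  pos <- fl[, "pos_ionisable"]; neg <- fl[, "neg_ionisable"]
  met <- fl[, "metal"]; hyd <- fl[, "hydrophobe"]; aro <- fl[, "aromatic"]
  xd <- fl[, "xbond_donor"]; xa <- fl[, "xbond_acceptor"]
  cc <- fl[, "carbonyl_carbon"]; co <- fl[, "carbonyl_oxygen"]
  accW <- acc | wacc

  feat[, "ionic"] <- ((pos[i] & neg[j]) | (neg[i] & pos[j])) &
    d <= .th(config, "ionic_dist_max")
  feat[, "metal"] <- ((met[i] & (acc[j] | neg[j])) |
                      (met[j] & (acc[i] | neg[i]))) &
    d <= .th(config, "metal_dist_max")
  feat[, "aromatic"] <- aro[i] & aro[j] & d <= .th(config, "aromatic_dist_max")
  feat[, "hydrophobic"] <- hyd[i] & hyd[j] &
    d <= .th(config, "hydrophobic_dist_max")
  feat[, "carbonyl"] <- ((cc[i] & co[j]) | (co[i] & cc[j])) &
    d <= .th(config, "carbonyl_dist_max")
  feat[, "polar"] <- ((don[i] & acc[j]) | (don[j] & acc[i])) &
    d <= .th(config, "polar_dist_max")
  feat[, "weak_polar"] <- ((wdon[i] & accW[j]) | (wdon[j] & accW[i]) |
                           (don[i] & wacc[j]) | (don[j] & wacc[i])) &
    d <= .th(config, "weak_polar_dist_max")

  elem <- a$element
  hydAt <- function(k) {
    hs <- adj[[k]][elem[adj[[k]]] == "H"]
    if (length(hs)) xyz[hs, , drop = FALSE] else NULL
  }
  # hydrogen bonds (both directions)
  cand <- which(((don[i] & acc[j]) | (don[j] & acc[i])) &
                d <= .th(config, "hbond_dist_max") & !suppressed)
  for (k in cand) {
    ok <- (don[i[k]] && acc[j[k]] &&
           detectHbond(xyz[i[k], ], hydAt(i[k]), xyz[j[k], ], config)) ||
          (don[j[k]] && acc[i[k]] &&
           detectHbond(xyz[j[k], ], hydAt(j[k]), xyz[i[k], ], config))
    feat[k, "hbond"] <- ok
  }
  # weak hydrogen bonds: C-H donor to acceptor, or donor to weak acceptor
  cand <- which(((wdon[i] & accW[j]) | (wdon[j] & accW[i]) |
                 (don[i] & wacc[j]) | (don[j] & wacc[i])) &
                d <= .th(config, "weak_hbond_dist_max") & !suppressed)
  for (k in cand) {
    ok <- ((wdon[i[k]] && accW[j[k]]) || (don[i[k]] && wacc[j[k]])) &&
      detectWeakHbond(xyz[i[k], ], hydAt(i[k]), xyz[j[k], ], config)
    ok <- ok ||
      (((wdon[j[k]] && accW[i[k]]) || (don[j[k]] && wacc[i[k]])) &&
       detectWeakHbond(xyz[j[k], ], hydAt(j[k]), xyz[i[k], ], config))
    feat[k, "weak_hbond"] <- ok
  }
  # halogen bonds
  cand <- which(((xd[i] & xa[j]) | (xd[j] & xa[i])) & !suppressed)
  for (k in cand) {
    pairsXA <- list()
    if (xd[i[k]] && xa[j[k]]) pairsXA <- c(pairsXA, list(c(i[k], j[k])))
    if (xd[j[k]] && xa[i[k]]) pairsXA <- c(pairsXA, list(c(j[k], i[k])))
    for (p in pairsXA) {
      x <- p[1]; acp <- p[2]
      cnb <- adj[[x]][elem[adj[[x]]] == "C"]
      if (!length(cnb)) {
        warning("halogen ", .atomIds(a, x), " has no bound carbon; ",
                "halogen-bond geometry undefined", call. = FALSE)
        next
      }
      if (detectXbond(xyz[x, ], xyz[cnb[1], ], xyz[acp, ], config,
                      halogen_element = elem[x],
                      acceptor_element = elem[acp])) {
        feat[k, "xbond"] <- TRUE
      }
    }
  }

  feat[suppressed, ] <- FALSE
  labels <- .entityLabels(a, i, j, selectionAtoms)
  .contactsDf(structure, pairs, cls, feat, labels)
}

.entityLabels <- function(a, i, j, selectionAtoms) {
  if (is.null(selectionAtoms)) {
    return(rep("intra_nonselection", length(i)))
  }
  inA <- i %in% selectionAtoms
  inB <- j %in% selectionAtoms
  nIn <- inA + inB
  water <- a$is_water[i] | a$is_water[j]
  ifelse(nIn == 2, "intra_selection",
    ifelse(nIn == 1, "inter",
      ifelse(water, "water_bridge_candidate", "intra_nonselection")))
}

.atomIds <- function(a, idx) {
  sprintf("%s/%s%s/%s", a$chain_id[idx], a$res_seq[idx], a$i_code[idx],
          a$name[idx])
}

.contactsDf <- function(structure, pairs, cls, feat, labels) {
  a <- structure@atoms
  i <- pairs$i; j <- pairs$j
  swap <- a$serial[i] > a$serial[j]
  if (any(swap)) {
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  df <- data.frame(
    i = i, j = j,
    atom_a = .atomIds(a, i), atom_b = .atomIds(a, j),
    serial_a = a$serial[i], serial_b = a$serial[j],
    distance = pairs$distance,
    distance_class = cls,
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(feat))
  df$entity <- labels
  ord <- order(df$serial_a, df$serial_b)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}
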