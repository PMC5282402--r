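# Planar-group perception: aromatic ring systems and amide groups.

# Cycle basis of a small undirected graph given as an adjacency list over
# the vertex subset `verts` (global atom indices).  Spanning-forest BFS;
# each non-tree edge closes one fundamental cycle.
.cycleBasis <- function(verts, adj) {
  local <- seq_along(verts)
  idx <- integer(max(verts))
  idx[verts] <- local
  nbrs <- lapply(verts, function(v) idx[adj[[v]][adj[[v]] %in% verts]])
  n <- length(verts)
  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  cycles <- list()
  seen_edge <- matrix(FALSE, n, n)
  for (root in seq_len(n)) {
    if (visited[root]) next
    queue <- root
    visited[root] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in nbrs[[u]]) {
        if (!visited[v]) {
          visited[v] <- TRUE
          parent[v] <- u
          seen_edge[u, v] <- seen_edge[v, u] <- TRUE
          queue <- c(queue, v)
        } else if (!seen_edge[u, v] && v != u) {
          seen_edge[u, v] <- seen_edge[v, u] <- TRUE
          pu <- u; pathu <- u
          while (!is.na(parent[pu])) { pu <- parent[pu]; pathu <- c(pathu, pu) }
          pv <- v; pathv <- v
          while (!is.na(parent[pv])) { pv <- parent[pv]; pathv <- c(pathv, pv) }
          common <- intersect(pathu, pathv)
          if (!length(common)) next
          anc <- common[1]
          cyc <- c(pathu[seq_len(match(anc, pathu))],
                   rev(pathv[seq_len(match(anc, pathv) - 1)]))
          cycles[[length(cycles) + 1L]] <- verts[cyc]
        }
      }
    }
  }
  cycles
}

# Aromatic ring perception on hetero groups: cycles of size 5 or 6 whose
# members are C/N/O/S, have at most 3 heavy neighbours (sp2-like), and whose
# RMS out-of-plane deviation is within the planarity tolerance.
.heteroRings <- function(structure, config) {
  a <- structure@atoms
  cls <- structure@residues$polymer_class[a$res_index]
  elig <- which(cls == "hetero" & a$element != "H" &
                !(a$element %in% config@options$metal_elements))
  if (length(elig) < 5) return(list())
  adj <- .adjacency(structure)
  elem <- a$element
  heavyAdj <- lapply(adj, function(nb) nb[elem[nb] != "H"])
  xyz <- .xyz(structure)
  cycles <- .cycleBasis(elig, heavyAdj)
  out <- list()
  seen <- character()
  for (cyc in cycles) {
    if (!(length(cyc) %in% c(5L, 6L))) next
    key <- paste(sort(cyc), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (!all(elem[cyc] %in% c("C", "N", "O", "S"))) next
    if (any(vapply(heavyAdj[cyc], length, 0L) > 3L)) next
    fit <- .planeFit(xyz[cyc, , drop = FALSE])
    if (fit$rms > .th(config, "planarity_tol")) next
    out[[length(out) + 1L]] <- list(
      members = cyc, centroid = fit$centroid, normal = fit$normal,
      rms = fit$rms, res_index = a$res_index[cyc[1]], source = "hetero")
  }
  out
}

#' Perceive aromatic ring systems
#'
#' Standard residues (Phe, Tyr, Trp, His, purines, pyrimidines) contribute
#' their dictionary-defined rings; hetero groups are searched for planar
#' 5/6-cycles of sp2-like C/N/O/S atoms.  Each ring carries the unweighted
#' centroid of its members and the unit normal of their least-squares plane.
#'
#' @param structure a \code{\link{PDBStructure-class}}.
#' @param dictionary typing dictionary (NULL = shipped).
#' @param config a \code{\link{GeometryConfig-class}} (NULL = default).
#' @return data.frame with one row per ring: ring_id, res_index, source,
#'   size, cx/cy/cz (centroid), nx/ny/nz (unit normal), rms, and a
#'   \code{members} list column of atom row indices.
#' @export
perceiveRings <- function(structure, dictionary = NULL, config = NULL) {
  dictionary <- .asDictionary(dictionary)
  config <- .asConfig(config)
  a <- structure@atoms
  xyz <- .xyz(structure)
  rings <- list()

  ring_defs <- dictionary$rings
  for (ri in seq_len(nrow(structure@residues))) {
    res <- structure@residues[ri, ]
    defs <- ring_defs[[.dictResName(res$res_name)]]
    if (is.null(defs)) next
    for (members_names in defs) {
      members <- vapply(members_names, function(nm) {
        k <- which(a$res_index == res$res_index & a$name == nm)
        if (length(k)) k[1] else NA_integer_
      }, 0L)
      if (anyNA(members)) {
        warning("ring in ", res$res_name, " ", res$chain_id, ":", res$res_seq,
                " skipped: member atom(s) missing", call. = FALSE)
        next
      }
      fit <- .planeFit(xyz[members, , drop = FALSE])
      rings[[length(rings) + 1L]] <- list(
        members = unname(members), centroid = fit$centroid,
        normal = fit$normal, rms = fit$rms, res_index = res$res_index,
        source = "dictionary")
    }
  }
  rings <- c(rings, .heteroRings(structure, config))
  .ringsToDf(rings)
}

.ringsToDf <- function(rings) {
  if (!length(rings)) {
    return(data.frame(ring_id = integer(), res_index = integer(),
                      source = character(), size = integer(),
                      cx = numeric(), cy = numeric(), cz = numeric(),
                      nx = numeric(), ny = numeric(), nz = numeric(),
                      rms = numeric(),
                      members = I(list())))
  }
  df <- data.frame(
    ring_id = seq_along(rings),
    res_index = vapply(rings, `[[`, 0L, "res_index"),
    source = vapply(rings, `[[`, "", "source"),
    size = vapply(rings, function(r) length(r$members), 0L),
    cx = vapply(rings, function(r) r$centroid[1], 0),
    cy = vapply(rings, function(r) r$centroid[2], 0),
    cz = vapply(rings, function(r) r$centroid[3], 0),
    nx = vapply(rings, function(r) r$normal[1], 0),
    ny = vapply(rings, function(r) r$normal[2], 0),
    nz = vapply(rings, function(r) r$normal[3], 0),
    rms = vapply(rings, `[[`, 0, "rms"),
    stringsAsFactors = FALSE)
  df$members <- I(lapply(rings, `[[`, "members"))
  df
}

#' Perceive amide groups
#'
#' One group per peptide bond (C and O of residue i with N of residue i+1),
#' per Asn/Gln side-chain amide, and per ligand amide (a carbonyl carbon
#' with a bonded nitrogen).  Centroid is the mean of the heavy C/O/N
#' coordinates; the normal is the unit normal of their plane.
#'
#' @param structure a typed \code{\link{PDBStructure-class}} (ligand amides
#'   need carbonyl flags).
#' @param dictionary typing dictionary (NULL = shipped).
#' @param config a \code{\link{GeometryConfig-class}} (NULL = default).
#' @return data.frame: group_id, kind (backbone/side_chain/ligand),
#'   centroid/normal columns, \code{members} and \code{parents} list columns
#'   (atom indices; parent residue indices).
#' @export
perceiveAmides <- function(structure, dictionary = NULL, config = NULL) {
  dictionary <- .asDictionary(dictionary)
  config <- .asConfig(config)
  a <- structure@atoms
  xyz <- .xyz(structure)
  r <- structure@residues
  find <- function(ri, nm) {
    k <- which(a$res_index == ri & a$name == nm)
    if (length(k)) k[1] else NA_integer_
  }
  groups <- list()
  addGroup <- function(cIdx, oIdx, nIdx, kind) {
    members <- c(cIdx, oIdx, nIdx)
    v1 <- xyz[oIdx, ] - xyz[cIdx, ]
    v2 <- xyz[nIdx, ] - xyz[cIdx, ]
    normal <- c(v1[2] * v2[3] - v1[3] * v2[2],
                v1[3] * v2[1] - v1[1] * v2[3],
                v1[1] * v2[2] - v1[2] * v2[1])
    if (.vnorm(normal) < 1e-8) return()  # collinear: no plane
    k <- which.max(abs(normal))
    if (normal[k] < 0) normal <- -normal
    groups[[length(groups) + 1L]] <<- list(
      members = members, centroid = colMeans(xyz[members, , drop = FALSE]),
      normal = normal / .vnorm(normal), kind = kind,
      parents = unique(a$res_index[members]))
  }

  pep <- which(r$polymer_class == "peptide")
  for (k in seq_along(pep)) {
    i <- pep[k]
    if (k == length(pep)) break
    j <- pep[k + 1]
    if (r$chain_id[i] != r$chain_id[j]) next
    cIdx <- find(r$res_index[i], "C"); oIdx <- find(r$res_index[i], "O")
    nIdx <- find(r$res_index[j], "N")
    if (anyNA(c(cIdx, oIdx, nIdx))) next
    if (.dist3(xyz[cIdx, ], xyz[nIdx, ]) > 1.7) next
    addGroup(cIdx, oIdx, nIdx, "backbone")
  }

  for (i in seq_len(nrow(r))) {
    defs <- dictionary$amides[[r$res_name[i]]]
    if (is.null(defs)) next
    for (d in defs) {
      idx <- vapply(d, function(nm) find(r$res_index[i], nm), 0L)
      if (anyNA(idx)) next
      addGroup(idx[1], idx[2], idx[3], "side_chain")
    }
  }

  if (structure@typed) {
    fl <- structure@flags
    adj <- .adjacency(structure)
    elem <- a$element
    cls <- r$polymer_class[a$res_index]
    lig_c <- which(fl[, "carbonyl_carbon"] & cls == "hetero")
    for (cIdx in lig_c) {
      nb <- adj[[cIdx]]
      oIdx <- nb[elem[nb] == "O" & fl[nb, "carbonyl_oxygen"]]
      nIdx <- nb[elem[nb] == "N"]
      if (length(oIdx) && length(nIdx)) {
        addGroup(cIdx, oIdx[1], nIdx[1], "ligand")
      }
    }
  }

  if (!length(groups)) {
    return(data.frame(group_id = integer(), kind = character(),
                      cx = numeric(), cy = numeric(), cz = numeric(),
                      nx = numeric(), ny = numeric(), nz = numeric(),
                      members = I(list()), parents = I(list())))
  }
  df <- data.frame(
    group_id = seq_along(groups),
    kind = vapply(groups, `[[`, "", "kind"),
    cx = vapply(groups, function(g) g$centroid[1], 0),
    cy = vapply(groups, function(g) g$centroid[2], 0),
    cz = vapply(groups, function(g) g$centroid[3], 0),
    nx = vapply(groups, function(g) g$normal[1], 0),
    ny = vapply(groups, function(g) g$normal[2], 0),
    nz = vapply(groups, function(g) g$normal[3], 0),
    stringsAsFactors = FALSE)
  df$members <- I(lapply(groups, `[[`, "members"))
  df$parents <- I(lapply(groups, `[[`, "parents"))
  df
}
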