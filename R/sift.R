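# Residue-level aggregation of contacts and group interactions into binary
# and integer structural interaction fingerprints.

# Scope predicate for group interactions: with an active selection, a
# group-level interaction is in scope iff exactly one side has atoms in it.
.groupInScope <- function(sideA, sideB, selectionAtoms) {
  if (is.null(selectionAtoms)) return(TRUE)
  inA <- any(sideA %in% selectionAtoms)
  inB <- any(sideB %in% selectionAtoms)
  xor(inA, inB)
}

#' Aggregate per-residue structural interaction fingerprints
#'
#' For every atom-level type (5 distance classes + 10 feature bits) the
#' integer fingerprint counts the residue's atoms making at least one
#' in-scope contact of that type (atoms, not contacts).  Ring and group
#' interactions count once per interaction, attributed to the parent
#' residue(s) of each side.  The binary fingerprint is count > 0.  A contact
#' between two residues contributes to both residues' fingerprints.  When a
#' selection is active, scope is restricted to inter-entity records.
#'
#' @param structure a typed \code{\link{PDBStructure-class}}.
#' @param contacts contact table from \code{\link{buildContacts}}.
#' @param ringInteractions,atomRingInteractions,groupInteractions,metInteractions
#'   tables from the plane-interaction detectors.
#' @param rings,amides the perception tables (needed to map interactions to
#'   member atoms for scope checks).
#' @param selectionAtoms integer atom indices of the active selection or
#'   NULL.
#' @return data.frame: residue identity columns, then for every type in
#'   \code{\link{SIFT_TYPES}} a \code{<type>_bin} and \code{<type>_count}
#'   column.  Residues with no in-scope record are absent.
#' @export
aggregateResidueSIFts <- function(structure, contacts,
                                  ringInteractions = NULL,
                                  atomRingInteractions = NULL,
                                  groupInteractions = NULL,
                                  metInteractions = NULL,
                                  rings = NULL, amides = NULL,
                                  selectionAtoms = NULL) {
  a <- structure@atoms
  r <- structure@residues
  nres <- nrow(r)
  counts <- matrix(0L, nres, length(SIFT_TYPES),
                   dimnames = list(NULL, SIFT_TYPES))

  sel_active <- !is.null(selectionAtoms)
  cc <- contacts
  if (sel_active && nrow(cc)) cc <- cc[cc$entity == "inter", , drop = FALSE]

  if (nrow(cc)) {
    # atoms (not contacts) making >= 1 contact of each atom-level type
    for (t in c(DISTANCE_CLASSES, FEATURE_BITS)) {
      hit <- if (t %in% DISTANCE_CLASSES) cc$distance_class == t else cc[[t]]
      atoms_t <- unique(c(cc$i[hit], cc$j[hit]))
      if (length(atoms_t)) {
        tab <- table(a$res_index[atoms_t])
        counts[as.integer(names(tab)), t] <- as.integer(tab)
      }
    }
  }

  bump <- function(res_idx, type, n = 1L) {
    for (ri in res_idx) counts[ri, type] <<- counts[ri, type] + n
  }
  ringMembers <- function(id) rings$members[[match(id, rings$ring_id)]]
  ringParent <- function(id) rings$res_index[match(id, rings$ring_id)]
  amideMembers <- function(id) amides$members[[match(id, amides$group_id)]]
  amideParents <- function(id) amides$parents[[match(id, amides$group_id)]]

  if (!is.null(ringInteractions) && nrow(ringInteractions)) {
    for (k in seq_len(nrow(ringInteractions))) {
      ma <- ringMembers(ringInteractions$ring_a[k])
      mb <- ringMembers(ringInteractions$ring_b[k])
      if (!.groupInScope(ma, mb, selectionAtoms)) next
      bump(unique(c(ringInteractions$res_a[k], ringInteractions$res_b[k])),
           "pi_pi")
    }
  }
  if (!is.null(atomRingInteractions) && nrow(atomRingInteractions)) {
    for (k in seq_len(nrow(atomRingInteractions))) {
      x <- atomRingInteractions[k, ]
      if (!.groupInScope(x$atom, ringMembers(x$ring_id), selectionAtoms)) next
      for (t in c("cation_pi", "donor_pi", "halogen_pi", "carbon_pi")) {
        if (isTRUE(x[[t]])) bump(unique(c(x$res_atom, x$res_ring)), t)
      }
    }
  }
  if (!is.null(groupInteractions) && nrow(groupInteractions)) {
    for (k in seq_len(nrow(groupInteractions))) {
      x <- groupInteractions[k, ]
      if (x$kind == "amide_amide") {
        ma <- amideMembers(x$group_a); mb <- amideMembers(x$group_b)
        if (!.groupInScope(ma, mb, selectionAtoms)) next
        bump(unique(c(amideParents(x$group_a), amideParents(x$group_b))),
             "amide_amide")
      } else {
        ma <- amideMembers(x$group_a); mb <- ringMembers(x$group_b)
        if (!.groupInScope(ma, mb, selectionAtoms)) next
        bump(unique(c(amideParents(x$group_a), ringParent(x$group_b))),
             "amide_ring")
      }
    }
  }
  if (!is.null(metInteractions) && nrow(metInteractions)) {
    for (k in seq_len(nrow(metInteractions))) {
      x <- metInteractions[k, ]
      if (!.groupInScope(x$atom, ringMembers(x$ring_id), selectionAtoms)) next
      bump(unique(c(x$res_atom, x$res_ring)), "met_aromatic")
    }
  }

  keep <- rowSums(counts) > 0
  out <- r[keep, c("chain_id", "res_seq", "i_code", "res_name"), drop = FALSE]
  for (t in SIFT_TYPES) {
    out[[paste0(t, "_bin")]] <- as.integer(counts[keep, t] > 0)
    out[[paste0(t, "_count")]] <- counts[keep, t]
  }
  rownames(out) <- NULL
  out
}

#' Summarise interactions over the active scope
#'
#' Per interaction type, the total number of in-scope contacts or group
#' interactions (contacts here, unlike the residue fingerprints which count
#' atoms).
#'
#' @inheritParams aggregateResidueSIFts
#' @return data.frame with columns \code{type} (in \code{SIFT_TYPES} order)
#'   and \code{count}.
#' @export
summariseInteractions <- function(contacts, ringInteractions = NULL,
                                  atomRingInteractions = NULL,
                                  groupInteractions = NULL,
                                  metInteractions = NULL,
                                  rings = NULL, amides = NULL,
                                  selectionAtoms = NULL) {
  counts <- setNames(integer(length(SIFT_TYPES)), SIFT_TYPES)
  sel_active <- !is.null(selectionAtoms)
  cc <- contacts
  if (sel_active && nrow(cc)) cc <- cc[cc$entity == "inter", , drop = FALSE]
  for (t in DISTANCE_CLASSES) counts[t] <- sum(cc$distance_class == t)
  for (t in FEATURE_BITS) counts[t] <- sum(cc[[t]])

  scopeRows <- function(df, sidesA, sidesB) {
    if (is.null(df) || !nrow(df)) return(df[integer(0), , drop = FALSE])
    keep <- vapply(seq_len(nrow(df)), function(k) {
      .groupInScope(sidesA(df, k), sidesB(df, k), selectionAtoms)
    }, TRUE)
    df[keep, , drop = FALSE]
  }
  ringMembers <- function(id) rings$members[[match(id, rings$ring_id)]]
  amideMembers <- function(id) amides$members[[match(id, amides$group_id)]]

  rr <- scopeRows(ringInteractions,
                  function(df, k) ringMembers(df$ring_a[k]),
                  function(df, k) ringMembers(df$ring_b[k]))
  counts["pi_pi"] <- if (is.null(rr)) 0L else nrow(rr)
  ar <- scopeRows(atomRingInteractions,
                  function(df, k) df$atom[k],
                  function(df, k) ringMembers(df$ring_id[k]))
  if (!is.null(ar) && nrow(ar)) {
    for (t in c("cation_pi", "donor_pi", "halogen_pi", "carbon_pi")) {
      counts[t] <- sum(ar[[t]])
    }
  }
  gr <- scopeRows(groupInteractions,
                  function(df, k) amideMembers(df$group_a[k]),
                  function(df, k) {
                    if (df$kind[k] == "amide_amide") amideMembers(df$group_b[k])
                    else ringMembers(df$group_b[k])
                  })
  if (!is.null(gr) && nrow(gr)) {
    counts["amide_amide"] <- sum(gr$kind == "amide_amide")
    counts["amide_ring"] <- sum(gr$kind == "amide_ring")
  }
  mr <- scopeRows(metInteractions,
                  function(df, k) df$atom[k],
                  function(df, k) ringMembers(df$ring_id[k]))
  counts["met_aromatic"] <- if (is.null(mr)) 0L else nrow(mr)

  data.frame(type = SIFT_TYPES, count = as.integer(counts),
             stringsAsFactors = FALSE)
}
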