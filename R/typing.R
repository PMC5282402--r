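# Physicochemical atom typing: dictionary-driven for standard polymer
# residues, connectivity-rule-driven for hetero groups; terminus correction
# and the histidine-ambiguity leniency switch.

.dictCache <- new.env(parent = emptyenv())

# Ribonucleotide names alias onto the deoxy entries (U onto DT).
.RIBO_ALIAS <- c(A = "DA", C = "DC", G = "DG", U = "DT", I = "DA", DI = "DA")

#' Load the typing dictionary
#'
#' Maps (residue name, atom name) to sets of physicochemical flags for the
#' 20 standard amino acids, nucleotides, waters and main-chain/terminus
#' atoms, plus aromatic-ring and side-chain-amide member lists.  The shipped
#' YAML can be copied and edited; see its comments for the schema.
#'
#' @param path YAML file; default is the dictionary shipped with the package.
#' @return a list with elements \code{backbone}, \code{overrides},
#'   \code{residues}, \code{rings}, \code{amides}.
#' @export
loadTypingDictionary <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.dictCache$default)) {
      .dictCache$default <- yaml::read_yaml(
        system.file("extdata", "typing_dictionary.yaml", package = "pdbSIFt",
                    mustWork = TRUE))
    }
    return(.dictCache$default)
  }
  yaml::read_yaml(path)
}

.asDictionary <- function(dictionary) {
  if (is.null(dictionary)) loadTypingDictionary() else dictionary
}

.dictResName <- function(res_name) {
  ifelse(res_name %in% names(.RIBO_ALIAS), .RIBO_ALIAS[res_name], res_name)
}

# Flags for one standard-residue atom, or NULL when unknown.
.dictLookup <- function(dictionary, res_name, atom_name, polymer_class) {
  res_name <- .dictResName(res_name)
  entry <- function(map) {
    if (!is.null(map) && atom_name %in% names(map)) {
      as.character(unlist(map[[atom_name]]))  # character(0) for empty entries
    } else NULL
  }
  fl <- entry(dictionary$overrides[[res_name]])
  if (is.null(fl)) fl <- entry(dictionary$residues[[res_name]])
  if (is.null(fl)) fl <- entry(dictionary$backbone[[polymer_class]])
  fl
}

# Adjacency list (atom index -> bonded atom indices) from the bond slot.
.adjacency <- function(structure) {
  n <- nrow(structure@atoms)
  adj <- vector("list", n)
  b <- structure@bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
      adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
    }
  }
  adj
}

#' Assign physicochemical type flags to every atom
#'
#' Standard polymer atoms are typed from the dictionary; hetero-group atoms
#' by connectivity rules over the inferred bond graph (any covalently bound
#' oxygen is an acceptor; halogens bonded to carbon are halogen-bond donors;
#' carbonyl C/O pairs are flagged in polymers and ligands alike).  Uniform
#' rules then add hydrophobe (C/S with no attached N/O/P; halogens on
#' carbon), weak donors (C-H carbons) and halogen-bond acceptors (every
#' H-bond acceptor).  Terminal main-chain atoms are corrected from the
#' dictionary and the histidine leniency switch applied.  Typing is
#' recomputed from scratch, so the operation is idempotent.
#'
#' @param structure a \code{\link{PDBStructure-class}}.
#' @param dictionary from \code{\link{loadTypingDictionary}} (NULL = shipped).
#' @param config a \code{\link{GeometryConfig-class}} (NULL = default).
#' @param lenient tautomer leniency: when TRUE both histidine ring nitrogens
#'   are typed donor + acceptor regardless of modelled hydrogens.
#' @param correctTermini run \code{\link{correctTerminalResidues}} (default
#'   TRUE).
#' @return the structure with its flag matrix filled in and
#'   \code{typed = TRUE}.
#' @export
assignAtomTypes <- function(structure, dictionary = NULL, config = NULL,
                            lenient = FALSE, correctTermini = TRUE) {
  dictionary <- .asDictionary(dictionary)
  config <- .asConfig(config)
  a <- structure@atoms
  n <- nrow(a)
  fl <- matrix(FALSE, n, length(ATOM_FLAGS),
               dimnames = list(NULL, ATOM_FLAGS))
  adj <- .adjacency(structure)
  elem <- a$element
  heavyAdj <- lapply(adj, function(nb) nb[elem[nb] != "H"])
  hasH <- vapply(adj, function(nb) any(elem[nb] == "H"), TRUE)

  cls <- structure@residues$polymer_class[a$res_index]
  is_metal <- elem %in% config@options$metal_elements & a$is_hetatm

  # --- dictionary typing for standard polymer residues and waters ---
  std <- which(cls %in% c("peptide", "nucleotide", "water") & elem != "H")
  unknown <- character()
  for (i in std) {
    flags <- .dictLookup(dictionary, a$res_name[i], a$name[i], cls[i])
    if (is.null(flags)) {
      unknown <- c(unknown, paste0(a$res_name[i], ":", a$name[i]))
    } else if (length(flags)) {
      fl[i, flags] <- TRUE
    }
  }
  if (length(unknown)) {
    warning("no dictionary entry for standard-residue atom(s): ",
            paste(unique(unknown), collapse = ", "), call. = FALSE)
  }

  # --- hetero rings first: aromatic ring membership informs N typing ---
  het_rings <- .heteroRings(structure, config)
  ring_atoms <- unique(unlist(lapply(het_rings, `[[`, "members")))
  if (length(ring_atoms)) fl[ring_atoms, "aromatic"] <- TRUE

  # --- connectivity rules for hetero-group atoms ---
  het <- which(cls == "hetero" & !is_metal & elem != "H")
  for (i in het) {
    nb <- heavyAdj[[i]]
    e <- elem[i]
    if (e == "O") {
      if (length(nb) == 0 && !hasH[i]) next  # isolated oxygen: untypable
      fl[i, "hbond_acceptor"] <- TRUE        # any covalently bound oxygen
      cnb <- nb[elem[nb] == "C"]
      carbonyl <- length(nb) == 1 && length(cnb) == 1 &&
        .bondLength(a, i, cnb) < 1.30 && .countOxygens(elem, heavyAdj, cnb) == 1
      if (carbonyl) {
        fl[i, "carbonyl_oxygen"] <- TRUE
      } else if (hasH[i] ||
                 (length(nb) == 1 && length(cnb) == 1 &&
                  .countOxygens(elem, heavyAdj, cnb) == 1)) {
        fl[i, "hbond_donor"] <- TRUE         # hydroxyl (modelled H or implied)
      }
      # carboxylate / phosphate / sulphate terminal oxygen
      if (length(nb) == 1) {
        parent <- nb[1]
        termO <- sum(vapply(heavyAdj[[parent]], function(x) {
          elem[x] == "O" && length(heavyAdj[[x]]) == 1
        }, TRUE))
        if ((elem[parent] == "C" && termO >= 2) ||
            (elem[parent] %in% c("P", "S") && termO >= 2)) {
          fl[i, "neg_ionisable"] <- TRUE
          fl[i, "hbond_donor"] <- FALSE
        }
      }
    } else if (e == "N") {
      guan <- any(vapply(nb, function(x) {
        elem[x] == "C" && sum(elem[heavyAdj[[x]]] == "N") >= 3
      }, TRUE))
      amide <- any(vapply(nb, function(x) {
        elem[x] == "C" && .isCarbonylCarbon(a, elem, heavyAdj, x)
      }, TRUE))
      aromaticN <- i %in% ring_atoms
      if (length(nb) >= 4) {
        fl[i, "pos_ionisable"] <- TRUE
        fl[i, "hbond_donor"] <- hasH[i]
      } else if (guan) {
        fl[i, c("hbond_donor", "pos_ionisable")] <- TRUE
      } else if (amide) {
        fl[i, "hbond_donor"] <- TRUE
      } else if (aromaticN) {
        if (hasH[i]) fl[i, "hbond_donor"] <- TRUE
        else fl[i, "hbond_acceptor"] <- TRUE
      } else if (hasH[i]) {
        fl[i, "hbond_donor"] <- TRUE
        if (length(nb) <= 2) fl[i, "hbond_acceptor"] <- TRUE
      } else if (length(nb) <= 2) {
        fl[i, c("hbond_donor", "hbond_acceptor")] <- TRUE  # ambiguous amine
      } else {
        fl[i, "hbond_acceptor"] <- TRUE                    # tertiary amine
      }
    } else if (e == "S") {
      if (length(nb) <= 1) fl[i, c("hbond_donor", "hbond_acceptor")] <- TRUE
      else fl[i, "hbond_acceptor"] <- TRUE
    } else if (e == "C") {
      if (.isCarbonylCarbon(a, elem, heavyAdj, i)) {
        fl[i, "carbonyl_carbon"] <- TRUE
      }
      guanC <- sum(elem[nb] == "N") >= 3
      if (guanC) fl[i, "pos_ionisable"] <- TRUE
    }
  }

  # --- halogens (polymer or hetero) ---
  hal <- which(elem %in% c("F", "CL", "BR", "I"))
  for (i in hal) {
    fl[i, "halogen"] <- TRUE
    onC <- any(elem[heavyAdj[[i]]] == "C")
    if (onC && elem[i] != "F") fl[i, "xbond_donor"] <- TRUE
    if (onC && isTRUE(config@options$halogen_weak_acceptor)) {
      fl[i, "weak_acceptor"] <- TRUE
    }
  }

  # --- uniform derived flags ---
  noNOP <- vapply(seq_len(n), function(i) {
    !any(elem[heavyAdj[[i]]] %in% c("N", "O", "P"))
  }, TRUE)
  fl[, "hydrophobe"] <- (elem %in% c("C", "S") & noNOP) |
    (fl[, "halogen"] & vapply(heavyAdj, function(nb) any(elem[nb] == "C"), TRUE))
  nNO <- vapply(heavyAdj, function(nb) sum(elem[nb] %in% c("N", "O")), 0L)
  fl[, "weak_donor"] <- elem == "C" & !fl[, "carbonyl_carbon"] & nNO < 2

  structure@flags <- fl
  structure@typed <- TRUE
  structure <- applyAmbiguityLeniency(structure, enabled = lenient)
  if (correctTermini) {
    structure <- correctTerminalResidues(structure, dictionary)
  }
  fl <- structure@flags

  # --- metal exclusivity and the acceptor->halogen-acceptor rule ---
  fl[is_metal, ] <- FALSE
  fl[is_metal, "metal"] <- TRUE
  fl[, "xbond_acceptor"] <- fl[, "hbond_acceptor"]
  structure@flags <- fl
  structure
}

.bondLength <- function(a, i, j) {
  sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
}

.countOxygens <- function(elem, heavyAdj, i) sum(elem[heavyAdj[[i]]] == "O")

# C double-bonded to exactly one terminal O (bond < 1.30 A) and carrying no
# second oxygen: a ketone/aldehyde/amide carbonyl, not a carboxylate.
.isCarbonylCarbon <- function(a, elem, heavyAdj, i) {
  if (elem[i] != "C") return(FALSE)
  onb <- heavyAdj[[i]][elem[heavyAdj[[i]]] == "O"]
  length(onb) == 1 && length(heavyAdj[[onb]]) == 1 &&
    .bondLength(a, i, onb) < 1.30
}

#' Correct terminal-residue main-chain types
#'
#' Terminal main-chain atoms get canonical terminus types even when sibling
#' atoms are unmodelled: a C-terminal carboxyl oxygen is acceptor + negative
#' even if OXT is absent (never a hydroxyl donor), and an N-terminal amine
#' nitrogen is donor + positive (proline: donor only when an H is attached).
#'
#' @param structure a typed \code{\link{PDBStructure-class}}.
#' @param dictionary typing dictionary (unused beyond the standard terminus
#'   semantics; kept for signature stability).
#' @return the structure with corrected flags.
#' @export
correctTerminalResidues <- function(structure, dictionary = NULL) {
  if (!structure@typed) stop("structure must be typed first")
  a <- structure@atoms
  r <- structure@residues
  fl <- structure@flags
  elem <- a$element
  adj <- .adjacency(structure)
  term <- r$terminal[a$res_index]
  pep <- r$polymer_class[a$res_index] == "peptide"

  cterm <- pep & term %in% c("c_term", "both") & a$name %in% c("O", "OXT")
  if (any(cterm)) {
    fl[cterm, ] <- FALSE
    fl[cterm, c("hbond_acceptor", "neg_ionisable", "xbond_acceptor")] <- TRUE
  }
  ctermC <- pep & term %in% c("c_term", "both") & a$name == "C"
  fl[ctermC, "carbonyl_carbon"] <- FALSE

  nterm <- which(pep & term %in% c("n_term", "both") & a$name == "N")
  for (i in nterm) {
    fl[i, "pos_ionisable"] <- TRUE
    hasH <- any(elem[adj[[i]]] == "H")
    fl[i, "hbond_donor"] <- if (a$res_name[i] == "PRO") hasH else TRUE
  }
  structure@flags <- fl
  structure
}

#' Apply (or remove) tautomeric-ambiguity leniency
#'
#' With leniency enabled, both histidine ring nitrogens (ND1, NE2) are typed
#' donor + acceptor, accommodating unknown protonation and flipped
#' histidines.  Disabled, donor/acceptor follow the explicitly modelled
#' hydrogens: an H on the ring nitrogen makes it a donor, otherwise it is an
#' acceptor only.  Other residues are untouched.
#'
#' @param structure a typed \code{\link{PDBStructure-class}}.
#' @param enabled logical.
#' @return the structure with updated histidine flags.
#' @export
applyAmbiguityLeniency <- function(structure, enabled = TRUE) {
  if (!structure@typed) stop("structure must be typed first")
  a <- structure@atoms
  fl <- structure@flags
  elem <- a$element
  adj <- .adjacency(structure)
  his <- which(a$res_name %in% c("HIS", "HID", "HIE", "HIP") &
               a$name %in% c("ND1", "NE2"))
  for (i in his) {
    if (enabled) {
      fl[i, c("hbond_donor", "hbond_acceptor")] <- TRUE
    } else {
      hasH <- any(elem[adj[[i]]] == "H")
      fl[i, "hbond_donor"] <- hasH
      fl[i, "hbond_acceptor"] <- !hasH
    }
  }
  fl[, "xbond_acceptor"] <- fl[, "hbond_acceptor"] & !fl[, "metal"]
  structure@flags <- fl
  structure
}
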