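#' @import methods
NULL

# ---------------------------------------------------------------------------
# Controlled vocabularies
# ---------------------------------------------------------------------------

#' Physicochemical atom flags
#'
#' The full set of per-atom physicochemical type flags an atom may carry
#' after typing.  An atom holds any subset, except that \code{metal} is
#' exclusive with every non-metal flag.
#' @export
ATOM_FLAGS <- c(
  "hbond_donor", "hbond_acceptor", "weak_donor", "weak_acceptor",
  "pos_ionisable", "neg_ionisable", "hydrophobe", "aromatic", "halogen",
  "xbond_donor", "xbond_acceptor", "metal", "carbonyl_oxygen",
  "carbonyl_carbon"
)

#' Mutually exclusive distance classes
#' @export
DISTANCE_CLASSES <- c("clash", "covalent", "vdw_clash", "vdw", "proximal")

#' Atom-atom feature interaction bits
#' @export
FEATURE_BITS <- c(
  "hbond", "weak_hbond", "xbond", "ionic", "metal", "aromatic",
  "hydrophobic", "carbonyl", "polar", "weak_polar"
)

#' Ring-level interaction subtypes
#' @export
PI_TYPES <- c("pi_pi", "cation_pi", "donor_pi", "halogen_pi", "carbon_pi")

#' Planar-group interaction subtypes
#' @export
GROUP_TYPES <- c("amide_amide", "amide_ring", "met_aromatic")

#' The 15 feature interaction subtypes of the classifier vocabulary
#' @export
FEATURE_SUBTYPES <- c(FEATURE_BITS, PI_TYPES)

#' Full per-residue fingerprint vocabulary (distance classes, atom features,
#' ring and group interactions)
#' @export
SIFT_TYPES <- c(DISTANCE_CLASSES, FEATURE_BITS, PI_TYPES, GROUP_TYPES)

# ---------------------------------------------------------------------------
# GeometryConfig
# ---------------------------------------------------------------------------

#' Geometric threshold configuration
#'
#' Holds every distance/angle threshold used by contact detection, the
#' covalent and van der Waals radii tables, and assorted options (water
#' residue names, metal elements, leniency switches).  Constructed by
#' \code{\link{defaultGeometryConfig}} or \code{\link{readGeometryConfig}}.
#'
#' @slot thresholds named numeric vector of distances (Angstrom) and angles
#'   (degrees).
#' @slot radii data.frame with columns \code{element}, \code{cov}, \code{vdw}.
#' @slot options list: \code{water_names}, \code{metal_elements},
#'   \code{halogen_weak_acceptor}, \code{sulphur_aromatic_residues}.
#' @export
setClass("GeometryConfig", representation(
  thresholds = "numeric",
  radii = "data.frame",
  options = "list"
))

setValidity("GeometryConfig", function(object) {
  th <- object@thresholds
  msgs <- character()
  dist_names <- grep("(_dist_max|_tol|cutoff|vdw_comp)$", names(th), value = TRUE)
  if (any(th[dist_names] <= 0)) {
    msgs <- c(msgs, "all distance thresholds must be > 0")
  }
  ang_names <- grep("angle", names(th), value = TRUE)
  if (any(th[ang_names] < 0 | th[ang_names] > 180)) {
    msgs <- c(msgs, "angles must lie in [0, 180] degrees")
  }
  atom_maxima <- c("hbond_dist_max", "weak_hbond_dist_max", "polar_dist_max",
                   "weak_polar_dist_max", "ionic_dist_max", "metal_dist_max",
                   "carbonyl_dist_max", "hydrophobic_dist_max",
                   "aromatic_dist_max")
  if (any(th[atom_maxima] > th[["cutoff"]])) {
    msgs <- c(msgs, "cutoff must be >= every atom-atom feature distance maximum")
  }
  if (!all(c("element", "cov", "vdw") %in% names(object@radii))) {
    msgs <- c(msgs, "radii table needs element/cov/vdw columns")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn GeometryConfig-class compact display
#' @param object a \code{GeometryConfig}
#' @export
setMethod("show", "GeometryConfig", function(object) {
  cat("GeometryConfig:", length(object@thresholds), "thresholds,",
      nrow(object@radii), "element radii\n")
  cat("  cutoff:", object@thresholds[["cutoff"]], "A\n")
})

# ---------------------------------------------------------------------------
# PDBStructure
# ---------------------------------------------------------------------------

#' Parsed macromolecular structure
#'
#' One model of a PDB file after alternate-location resolution.  Atoms live
#' in a data.frame in file order; residue-level metadata (polymer class,
#' terminus marks) and the inferred covalent bond graph are carried
#' alongside.  Physicochemical flags are all-FALSE until
#' \code{\link{assignAtomTypes}} runs.
#'
#' @slot atoms data.frame: serial, name, alt_loc, res_name, chain_id,
#'   res_seq, i_code, element, x, y, z, occupancy, is_hetatm, is_water,
#'   res_index.
#' @slot residues data.frame: res_index, chain_id, res_seq, i_code, res_name,
#'   polymer_class (peptide/nucleotide/hetero/water), terminal (none, n_term,
#'   c_term, five_prime, three_prime, both).
#' @slot flags logical matrix, atoms x \code{\link{ATOM_FLAGS}}.
#' @slot bonds integer matrix, one row per inferred covalent bond
#'   (atom indices into \code{atoms}).
#' @slot dropped data.frame logging records removed during parsing.
#' @slot typed logical; TRUE once atom typing has run.
#' @export
setClass("PDBStructure", representation(
  atoms = "data.frame",
  residues = "data.frame",
  flags = "matrix",
  bonds = "matrix",
  dropped = "data.frame",
  typed = "logical"
))

setValidity("PDBStructure", function(object) {
  a <- object@atoms
  msgs <- character()
  if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z))) {
    msgs <- c(msgs, "atom coordinates must be finite")
  }
  if (any(!nzchar(a$element))) {
    msgs <- c(msgs, "every atom needs a non-empty element symbol")
  }
  key <- paste(a$chain_id, a$res_seq, a$i_code, a$name, sep = "\r")
  if (anyDuplicated(key)) {
    msgs <- c(msgs, "duplicate (chain, res_seq, i_code, name) after alt-loc resolution")
  }
  if (nrow(object@flags) != nrow(a) ||
      !identical(colnames(object@flags), ATOM_FLAGS)) {
    msgs <- c(msgs, "flags matrix must be atoms x ATOM_FLAGS")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PDBStructure-class compact display
#' @param object a \code{PDBStructure}
#' @export
setMethod("show", "PDBStructure", function(object) {
  a <- object@atoms
  r <- object@residues
  cat("PDBStructure:", nrow(a), "atoms,", nrow(r), "residues,",
      length(unique(a$chain_id)), "chain(s)\n")
  cls <- table(r$polymer_class)
  cat("  residues:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  cat("  typed:", object@typed, "|", nrow(object@bonds), "inferred bonds\n")
})

# ---------------------------------------------------------------------------
# ContactSelection
# ---------------------------------------------------------------------------

#' Parsed selection expression
#'
#' A selection is one or more whitespace-separated items of the form
#' \code{/chain/resseq[icode]/atomname}; an empty component is a wildcard.
#' Resolved against a structure it yields the union of the per-item matches.
#'
#' @slot items data.frame with character columns chain, res, atom (empty
#'   string = wildcard).
#' @slot text the original expression(s).
#' @export
setClass("ContactSelection", representation(
  items = "data.frame",
  text = "character"
))

#' @describeIn ContactSelection-class compact display
#' @param object a \code{ContactSelection}
#' @export
setMethod("show", "ContactSelection", function(object) {
  cat("ContactSelection:", nrow(object@items), "item(s):",
      paste(object@text, collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# ContactResult
# ---------------------------------------------------------------------------

#' Full result of an interaction calculation
#'
#' Returned by \code{\link{calculateInteractions}} / \code{\link{runContacts}}.
#'
#' @slot structure the typed \code{\link{PDBStructure}}.
#' @slot contacts data.frame of atom-atom contacts with distance class and
#'   feature bits.
#' @slot rings perceived \code{RingSystem} table.
#' @slot amides perceived amide-group table.
#' @slot ringInteractions pi-pi ring-ring records.
#' @slot atomRingInteractions cation/donor/halogen/carbon-pi records.
#' @slot groupInteractions amide-amide and amide-ring records.
#' @slot metInteractions Met/thioether sulphur-aromatic records.
#' @slot residueSIFts per-residue binary + count fingerprints.
#' @slot summary per-type totals over the active scope.
#' @slot selection the \code{ContactSelection} used (may have zero items).
#' @slot config the \code{GeometryConfig} used.
#' @export
setClass("ContactResult", representation(
  structure = "PDBStructure",
  contacts = "data.frame",
  rings = "data.frame",
  amides = "data.frame",
  ringInteractions = "data.frame",
  atomRingInteractions = "data.frame",
  groupInteractions = "data.frame",
  metInteractions = "data.frame",
  residueSIFts = "data.frame",
  summary = "data.frame",
  selection = "ContactSelection",
  config = "GeometryConfig"
))

#' @describeIn ContactResult-class compact display
#' @param object a \code{ContactResult}
#' @export
setMethod("show", "ContactResult", function(object) {
  cat("ContactResult:", nrow(object@contacts), "contacts,",
      nrow(object@ringInteractions), "pi-pi,",
      nrow(object@atomRingInteractions), "atom-ring,",
      nrow(object@groupInteractions), "group interactions\n")
  feat <- object@summary
  feat <- feat[feat$count > 0 & feat$type %in% c(FEATURE_BITS, PI_TYPES, GROUP_TYPES), ]
  if (nrow(feat)) {
    cat("  features:", paste(feat$type, feat$count, sep = "=", collapse = ", "), "\n")
  }
})

# ---------------------------------------------------------------------------
# Accessor generics
# ---------------------------------------------------------------------------

#' Atom table of a structure or result
#' @param x a \code{PDBStructure} or \code{ContactResult}
#' @return data.frame of atoms
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "PDBStructure", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "ContactResult", function(x) x@structure@atoms)

#' Residue table
#' @param x a \code{PDBStructure} or \code{ContactResult}
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname residues
#' @export
setMethod("residues", "PDBStructure", function(x) x@residues)

#' @rdname residues
#' @export
setMethod("residues", "ContactResult", function(x) x@structure@residues)

#' Physicochemical flag matrix (atoms x ATOM_FLAGS)
#' @param x a \code{PDBStructure}
#' @export
setGeneric("typeFlags", function(x) standardGeneric("typeFlags"))

#' @rdname typeFlags
#' @export
setMethod("typeFlags", "PDBStructure", function(x) x@flags)

#' Inferred covalent bond list (2-column atom-index matrix)
#' @param x a \code{PDBStructure}
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname bonds
#' @export
setMethod("bonds", "PDBStructure", function(x) x@bonds)

#' Contact table of a result
#' @param x a \code{ContactResult}
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' @rdname contacts
#' @export
setMethod("contacts", "ContactResult", function(x) x@contacts)

#' Per-residue fingerprint table of a result
#' @param x a \code{ContactResult}
#' @export
setGeneric("residueSIFts", function(x) standardGeneric("residueSIFts"))

#' @rdname residueSIFts
#' @export
setMethod("residueSIFts", "ContactResult", function(x) x@residueSIFts)
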