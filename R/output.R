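# Pipeline orchestration, entity-scoped calculation, TSV writers.

#' Calculate all interatomic interactions for a structure
#'
#' The full pipeline: parse (unless given a \code{PDBStructure}), type
#' atoms, perceive rings and amides, enumerate and classify contacts,
#' detect ring/amide/sulphur group interactions, and aggregate residue
#' fingerprints and summary totals.
#'
#' @param pdb a file path, PDB text, or a \code{\link{PDBStructure-class}}.
#' @param selection a selection expression string (or
#'   \code{\link{ContactSelection-class}}), or NULL for the whole structure.
#' @param config a \code{\link{GeometryConfig-class}}, a YAML path, or NULL.
#' @param lenient histidine tautomer leniency (see
#'   \code{\link{applyAmbiguityLeniency}}).
#' @param model 1-based model number.
#' @return a \code{\link{ContactResult-class}}.
#' @examples
#' res <- calculateInteractions(makeFixture("hbond", "ideal"))
#' contacts(res)
#' @export
calculateInteractions <- function(pdb, selection = NULL, config = NULL,
                                  lenient = FALSE, model = 1L) {
  config <- .asConfig(config)
  structure <- if (is(pdb, "PDBStructure")) pdb else {
    readStructure(pdb, model = model, config = config)
  }
  if (!structure@typed) {
    structure <- assignAtomTypes(structure, config = config,
                                 lenient = lenient)
  }

  sel <- if (is.null(selection)) {
    new("ContactSelection",
        items = data.frame(chain = character(), res = character(),
                           atom = character(), stringsAsFactors = FALSE),
        text = character())
  } else if (is.character(selection)) {
    parseSelection(paste(selection, collapse = " "))
  } else selection
  selAtoms <- if (nrow(sel@items)) resolveSelection(sel, structure) else NULL

  rings <- perceiveRings(structure, config = config)
  amides <- perceiveAmides(structure, config = config)
  cts <- buildContacts(structure, config = config, selectionAtoms = selAtoms)
  rr <- ringRingInteractions(rings, config = config)
  ar <- atomRingInteractions(structure, rings, config = config)
  gr <- amideGroupInteractions(amides, rings, config = config)
  mr <- metSulphurAromatic(structure, rings, config = config)
  sifts <- aggregateResidueSIFts(structure, cts, rr, ar, gr, mr,
                                 rings = rings, amides = amides,
                                 selectionAtoms = selAtoms)
  summ <- summariseInteractions(cts, rr, ar, gr, mr, rings = rings,
                                amides = amides, selectionAtoms = selAtoms)

  new("ContactResult", structure = structure, contacts = cts, rings = rings,
      amides = amides, ringInteractions = rr, atomRingInteractions = ar,
      groupInteractions = gr, metInteractions = mr, residueSIFts = sifts,
      summary = summ, selection = sel, config = config)
}

#' Run the full calculation and write tabular outputs
#'
#' The command-line entry point's workhorse: reads a PDB file, runs
#' \code{\link{calculateInteractions}}, and writes six tab-separated files
#' next to the input (or into \code{outputDir}): \code{<stem>.contacts.tsv},
#' \code{.rings.tsv}, \code{.atom_rings.tsv}, \code{.groups.tsv},
#' \code{.residue_sifts.tsv} and \code{.summary.tsv}.
#'
#' @param pdbPath path to a PDB file.
#' @param selections character vector of selection expressions (combined as
#'   a union); empty for whole-structure calculation.
#' @param config a \code{GeometryConfig}, YAML path, or NULL.
#' @param lenient histidine tautomer leniency flag.
#' @param model 1-based model number.
#' @param outputDir output directory (default: alongside the input).
#' @param verbose log dropped records and typing warnings to stderr.
#' @return the \code{\link{ContactResult-class}}, invisibly.  Errors carry
#'   condition classes \code{pdbsift_input_error} (unreadable input) and
#'   \code{pdbsift_selection_error} (selection matched no atoms) so callers
#'   can map them to exit codes.
#' @export
runContacts <- function(pdbPath, selections = character(), config = NULL,
                        lenient = FALSE, model = 1L, outputDir = NULL,
                        verbose = FALSE) {
  if (!is.character(pdbPath) || length(pdbPath) != 1 ||
      !file.exists(pdbPath) || dir.exists(pdbPath)) {
    stop(structure(class = c("pdbsift_input_error", "error", "condition"),
                   list(message = paste0("cannot read input file: ", pdbPath),
                        call = NULL)))
  }
  config <- .asConfig(config)
  selections <- selections[nzchar(selections)]
  sel <- if (length(selections)) {
    parseSelection(paste(selections, collapse = " "))
  } else NULL

  structure <- readStructure(pdbPath, model = model, config = config)
  if (!is.null(sel)) {
    hits <- resolveSelection(sel, structure)
    if (!length(hits)) {
      stop(structure(class = c("pdbsift_selection_error", "error",
                               "condition"),
                     list(message = "selection matched no atoms",
                          call = NULL)))
    }
  }
  result <- calculateInteractions(structure, selection = sel,
                                  config = config, lenient = lenient)
  if (verbose && nrow(result@structure@dropped)) {
    message("dropped records:")
    d <- result@structure@dropped
    for (k in seq_len(nrow(d))) message("  ", d$record[k], ": ", d$reason[k])
  }

  stem <- sub("\\.(pdb|ent)$", "", basename(pdbPath), ignore.case = TRUE)
  dir <- if (is.null(outputDir)) dirname(pdbPath) else outputDir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- function(suffix) file.path(dir, paste0(stem, ".", suffix))
  writeContactsTSV(result@contacts, path("contacts.tsv"))
  writeRingsTSV(result, path("rings.tsv"))
  writeAtomRingsTSV(result, path("atom_rings.tsv"))
  writeGroupsTSV(result, path("groups.tsv"))
  writeResidueSIFtsTSV(result@residueSIFts, path("residue_sifts.tsv"))
  writeSummaryTSV(result@summary, path("summary.tsv"))
  invisible(result)
}

.fmt3 <- function(x) sprintf("%.3f", x)
.fmt1 <- function(x) sprintf("%.1f", x)

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
}

#' Write the atom-atom contact table
#'
#' One row per contact, sorted by (serial_a, serial_b): atom identifiers
#' (\code{chain/resseq[icode]/name}), distance to 3 decimals, entity label,
#' then one 0/1 column per SIFt bit in fixed order: the five distance
#' classes then the ten feature bits.  Identical input yields byte-identical
#' output.
#'
#' @param contacts contact table from \code{\link{buildContacts}} (or a
#'   \code{ContactResult}).
#' @param path output file.
#' @export
writeContactsTSV <- function(contacts, path) {
  if (is(contacts, "ContactResult")) contacts <- contacts@contacts
  df <- data.frame(atom_a = contacts$atom_a, atom_b = contacts$atom_b,
                   distance = .fmt3(contacts$distance),
                   entity = contacts$entity, stringsAsFactors = FALSE)
  for (t in DISTANCE_CLASSES) {
    df[[t]] <- as.integer(contacts$distance_class == t)
  }
  for (t in FEATURE_BITS) df[[t]] <- as.integer(contacts[[t]])
  .writeTSV(df, path)
}

#' Read a contacts TSV back into a data.frame
#'
#' Inverse of \code{\link{writeContactsTSV}} (bit columns become logicals,
#' the distance class a factor-free character column).
#' @param path a contacts TSV.
#' @export
readContactsTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$distance_class <- apply(df[DISTANCE_CLASSES] == 1, 1, function(r) {
    DISTANCE_CLASSES[which(r)]
  })
  for (t in FEATURE_BITS) df[[t]] <- df[[t]] == 1
  df[DISTANCE_CLASSES] <- NULL
  df
}

#' @describeIn writeContactsTSV pi-pi ring interactions (ring residues,
#'   centroid distance, interplanar angle, geometry label).
#' @param result a \code{ContactResult}.
#' @export
writeRingsTSV <- function(result, path) {
  rr <- result@ringInteractions
  r <- result@structure@residues
  resid <- function(ri) {
    k <- match(ri, r$res_index)
    sprintf("%s/%s%s/%s", r$chain_id[k], r$res_seq[k], r$i_code[k],
            r$res_name[k])
  }
  df <- data.frame(ring_a = rr$ring_a, res_a = if (nrow(rr)) resid(rr$res_a) else character(),
                   ring_b = rr$ring_b, res_b = if (nrow(rr)) resid(rr$res_b) else character(),
                   distance = .fmt3(rr$distance), theta = .fmt1(rr$theta),
                   geometry = rr$geometry, stringsAsFactors = FALSE)
  .writeTSV(df, path)
}

#' @describeIn writeContactsTSV atom-ring interactions with their
#'   non-exclusive subtypes.
#' @export
writeAtomRingsTSV <- function(result, path) {
  ar <- result@atomRingInteractions
  df <- data.frame(atom = ar$atom_id, ring = ar$ring_id,
                   distance = .fmt3(ar$distance), theta = .fmt1(ar$theta),
                   cation_pi = as.integer(ar$cation_pi),
                   donor_pi = as.integer(ar$donor_pi),
                   halogen_pi = as.integer(ar$halogen_pi),
                   carbon_pi = as.integer(ar$carbon_pi),
                   stringsAsFactors = FALSE)
  .writeTSV(df, path)
}

#' @describeIn writeContactsTSV amide-amide, amide-ring and sulphur-aromatic
#'   group interactions (for Met rows the angle column is the sulphur's
#'   elevation above the ring plane).
#' @export
writeGroupsTSV <- function(result, path) {
  gr <- result@groupInteractions
  df <- data.frame(kind = gr$kind, group_a = as.character(gr$group_a),
                   group_b = as.character(gr$group_b),
                   distance = .fmt3(gr$distance), angle = .fmt1(gr$theta),
                   stringsAsFactors = FALSE)
  mr <- result@metInteractions
  if (nrow(mr)) {
    df <- rbind(df, data.frame(kind = "met_aromatic", group_a = mr$atom_id,
                               group_b = as.character(mr$ring_id),
                               distance = .fmt3(mr$distance),
                               angle = .fmt1(mr$elevation),
                               stringsAsFactors = FALSE))
  }
  .writeTSV(df, path)
}

#' @describeIn writeContactsTSV per-residue binary + count fingerprints.
#' @param sifts residue fingerprint table.
#' @export
writeResidueSIFtsTSV <- function(sifts, path) {
  .writeTSV(sifts, path)
}

#' @describeIn writeContactsTSV per-type totals.
#' @param summary summary table.
#' @export
writeSummaryTSV <- function(summary, path) {
  .writeTSV(summary, path)
}
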