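# Structure input: PDB parsing, model selection, alt-loc resolution,
# polymer connectivity and terminus marking, selections, entity detection.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
NUC3 <- c("DA", "DC", "DG", "DT", "DI", "A", "C", "G", "U", "I")

.TWO_LETTER_ELEMENTS <- c("CL", "BR", "SE", "ZN", "FE", "MG", "MN", "CU",
                          "NI", "CO", "CD", "HG", "NA", "LI", "RB", "CS",
                          "SR", "BA", "AS")

# ---------------------------------------------------------------------------
# readStructure
# ---------------------------------------------------------------------------

#' Read one model of a PDB-format structure
#'
#' Parses fixed-column PDB text (via bio3d), keeps the requested model only,
#' resolves alternate locations (highest occupancy wins, ties broken by
#' alphabetical altLoc), flags waters and hetero groups, infers the covalent
#' bond graph from interatomic distances (plus CONECT records), identifies
#' polymer chains by inter-residue connectivity (peptide C-N <= 1.7 A,
#' nucleotide O3'-P <= 1.8 A) and marks terminal residues.
#'
#' @param pdb a file path, or PDB text (single string with newlines, or a
#'   character vector of lines).
#' @param model 1-based model number (default 1; NMR ensembles are never
#'   averaged).
#' @param config a \code{\link{GeometryConfig-class}} (radii and water names).
#' @return a \code{\link{PDBStructure-class}} object (untyped).
#' @examples
#' pdb <- makeFixture("hbond", "ideal")
#' s <- readStructure(pdb)
#' atoms(s)
#' @export
readStructure <- function(pdb, model = 1L, config = NULL) {
  config <- .asConfig(config)
  lines <- .pdbLines(pdb)

  model_starts <- grep("^MODEL ", lines)
  n_models <- max(1L, length(model_starts))
  if (model < 1L || model > n_models) {
    stop("model ", model, " out of range: file has ", n_models, " model(s)")
  }
  if (length(model_starts)) {
    ends <- grep("^ENDMDL", lines)
    start <- model_starts[model]
    end <- ends[ends > start][1]
    if (is.na(end)) end <- length(lines) + 1L
    block <- lines[seq(start + 1L, end - 1L)]
  } else {
    block <- lines
  }
  conect_lines <- grep("^CONECT", lines, value = TRUE)
  atom_lines <- grep("^(ATOM  |HETATM)", block)
  if (!length(atom_lines)) stop("no ATOM or HETATM records in the input")

  keep <- block[sort(unique(c(
    atom_lines, grep("^TER", block)
  )))]
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(c(keep, "END"), tf)
  p <- suppressWarnings(bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE))
  a <- p$atom

  blank <- function(v) ifelse(is.na(v), "", trimws(v))
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    alt_loc = blank(a$alt),
    res_name = trimws(a$resid),
    chain_id = blank(a$chain),
    res_seq = as.integer(a$resno),
    i_code = blank(a$insert),
    element = .normaliseElement(blank(a$elesy), trimws(a$elety),
                                a$type == "HETATM"),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    is_hetatm = a$type == "HETATM",
    stringsAsFactors = FALSE
  )

  res <- .resolveAltLocs(atoms)
  atoms <- res$atoms
  dropped <- res$dropped

  atoms$is_water <- atoms$res_name %in% config@options$water_names
  rkey <- paste(atoms$chain_id, atoms$res_seq, atoms$i_code, atoms$res_name,
                sep = "\r")
  atoms$res_index <- as.integer(factor(rkey, levels = unique(rkey)))

  residues <- atoms[!duplicated(atoms$res_index),
                    c("res_index", "chain_id", "res_seq", "i_code", "res_name")]
  rownames(residues) <- NULL
  residues$polymer_class <- ifelse(
    residues$res_name %in% config@options$water_names, "water",
    ifelse(residues$res_name %in% AA3, "peptide",
           ifelse(residues$res_name %in% NUC3, "nucleotide", "hetero")))
  residues$terminal <- "none"

  structure <- new("PDBStructure",
    atoms = atoms,
    residues = residues,
    flags = matrix(FALSE, nrow(atoms), length(ATOM_FLAGS),
                   dimnames = list(NULL, ATOM_FLAGS)),
    bonds = matrix(integer(), 0, 2),
    dropped = dropped,
    typed = FALSE)

  structure@bonds <- .inferBonds(structure, config, conect_lines)
  structure@residues <- .markTermini(structure)
  validObject(structure)
  structure
}

.pdbLines <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb, fixed = TRUE) && file.exists(pdb)) {
    return(readLines(pdb, warn = FALSE))
  }
  if (length(pdb) == 1) return(strsplit(pdb, "\n", fixed = TRUE)[[1]])
  pdb
}

# Element symbol: use the element column when present (D counts as H);
# otherwise infer from the atom name by the PDB alignment convention.
.normaliseElement <- function(elesy, name, hetatm) {
  out <- toupper(elesy)
  out[out == "D"] <- "H"
  missing <- !nzchar(out)
  if (any(missing)) {
    nm <- toupper(gsub("[0-9']", "", name[missing]))
    het <- hetatm[missing]
    two <- nchar(nm) >= 2 & substr(nm, 1, 2) %in% .TWO_LETTER_ELEMENTS & het
    inferred <- ifelse(two, substr(nm, 1, 2), substr(nm, 1, 1))
    inferred[inferred == "D"] <- "H"
    out[missing] <- inferred
  }
  out
}

# Keep the highest-occupancy alternate location per (chain, res, icode, name);
# ties broken by alphabetical altLoc id.  Exact duplicate records are dropped
# with a reason.
.resolveAltLocs <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$i_code, atoms$res_name,
               atoms$name, sep = "\r")
  ord <- order(factor(key, levels = unique(key)),
               -atoms$occupancy, atoms$alt_loc)
  sorted <- atoms[ord, ]
  skey <- key[ord]
  keep_first <- !duplicated(skey)
  dropped_rows <- sorted[!keep_first, ]
  reason <- ifelse(nzchar(dropped_rows$alt_loc),
                   paste0("alternate location '", dropped_rows$alt_loc,
                          "' not selected"),
                   "duplicate atom record")
  dropped <- data.frame(
    record = sprintf("%s %s/%s%s/%s", dropped_rows$res_name,
                     dropped_rows$chain_id, dropped_rows$res_seq,
                     dropped_rows$i_code, dropped_rows$name),
    reason = reason, stringsAsFactors = FALSE)
  kept <- sorted[keep_first, ]
  kept <- kept[order(match(paste(kept$chain_id, kept$res_seq, kept$i_code,
                                 kept$res_name, kept$name, sep = "\r"),
                           unique(key))), ]
  rownames(kept) <- NULL
  list(atoms = kept, dropped = dropped)
}

# Covalent bonds: pairs with d <= rcov_a + rcov_b + bond_tol (metals excluded:
# coordination is not covalence here), plus any CONECT pairs present.
.inferBonds <- function(structure, config, conect_lines = character()) {
  a <- structure@atoms
  n <- nrow(a)
  if (n < 2) return(matrix(integer(), 0, 2))
  radii <- lookupRadii(a$element, config)
  is_metal <- a$element %in% config@options$metal_elements
  max_reach <- 2 * max(radii$cov[!is_metal], 0.8) + .th(config, "bond_tol")
  cand <- .gridPairs(.xyz(structure), max_reach)
  if (nrow(cand)) {
    limit <- radii$cov[cand$i] + radii$cov[cand$j] + .th(config, "bond_tol")
    ok <- cand$distance <= limit & cand$distance > 0.4 &
      !is_metal[cand$i] & !is_metal[cand$j] &
      !(a$element[cand$i] == "H" & a$element[cand$j] == "H")
    bonds <- cbind(cand$i[ok], cand$j[ok])
  } else {
    bonds <- matrix(integer(), 0, 2)
  }
  if (length(conect_lines)) {
    ser <- lapply(conect_lines, function(l) {
      fields <- substring(l, seq(7, 27, 5), seq(11, 31, 5))
      as.integer(fields[nzchar(trimws(fields))])
    })
    extra <- do.call(rbind, lapply(ser, function(s) {
      s <- s[!is.na(s)]
      if (length(s) < 2) return(NULL)
      idx <- match(s, a$serial)
      idx <- idx[!is.na(idx)]
      if (length(idx) < 2) return(NULL)
      cbind(idx[1], idx[-1])
    }))
    if (!is.null(extra)) {
      extra <- t(apply(extra, 1, sort))
      bonds <- rbind(bonds, extra)
    }
  }
  if (nrow(bonds)) bonds <- unique(bonds)
  storage.mode(bonds) <- "integer"
  bonds
}

# Polymer segments: consecutive same-chain residues joined by a peptide
# (C-N <= 1.7 A) or nucleotide (O3'-P <= 1.8 A) link.  First residue of a
# segment is the N/5' terminus, last the C/3' terminus; a lone residue is
# "both".
.markTermini <- function(structure) {
  a <- structure@atoms
  r <- structure@residues
  coord <- function(ri, nm) {
    k <- which(a$res_index == ri & a$name == nm)
    if (length(k)) c(a$x[k[1]], a$y[k[1]], a$z[k[1]]) else NULL
  }
  linked <- function(i, j) {
    if (r$chain_id[i] != r$chain_id[j]) return(FALSE)
    if (r$polymer_class[i] == "peptide" && r$polymer_class[j] == "peptide") {
      p <- coord(r$res_index[i], "C"); q <- coord(r$res_index[j], "N")
      return(!is.null(p) && !is.null(q) && .dist3(p, q) <= 1.7)
    }
    if (r$polymer_class[i] == "nucleotide" &&
        r$polymer_class[j] == "nucleotide") {
      p <- coord(r$res_index[i], "O3'"); q <- coord(r$res_index[j], "P")
      return(!is.null(p) && !is.null(q) && .dist3(p, q) <= 1.8)
    }
    FALSE
  }
  is_poly <- r$polymer_class %in% c("peptide", "nucleotide")
  n <- nrow(r)
  link_next <- rep(FALSE, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (is_poly[i] && is_poly[i + 1]) link_next[i] <- linked(i, i + 1)
    }
  }
  first <- is_poly & !c(FALSE, link_next[-n])
  last <- is_poly & !link_next
  lab <- function(cls, f, l) {
    if (f && l) return("both")
    if (f) return(if (cls == "peptide") "n_term" else "five_prime")
    if (l) return(if (cls == "peptide") "c_term" else "three_prime")
    "none"
  }
  r$terminal <- vapply(seq_len(n), function(i) {
    if (!is_poly[i]) "none" else lab(r$polymer_class[i], first[i], last[i])
  }, "")
  r
}

# ---------------------------------------------------------------------------
# Selections
# ---------------------------------------------------------------------------

#' Parse a selection expression
#'
#' A selection is one or more whitespace-separated items of the form
#' \code{/chain/resseq[icode]/atomname}; any component may be empty, meaning
#' wildcard.  \code{"/A//"} selects all of chain A; \code{"/A/38/ /B//"}
#' selects residue A:38 plus all of chain B.
#'
#' @param expr selection expression string (or vector of item strings).
#' @return a \code{\link{ContactSelection-class}}.
#' @export
parseSelection <- function(expr) {
  items <- unlist(strsplit(expr, "[[:space:]]+"))
  items <- items[nzchar(items)]
  parts <- lapply(items, function(it) {
    if (!grepl("^/[^/]*/[^/]*/[^/]*$", it)) {
      stop("malformed selection item '", it,
           "': expected /chain/resseq[icode]/atomname")
    }
    comp <- strsplit(sub("^/", "", paste0(it, "\x01")), "/", fixed = TRUE)[[1]]
    trimws(sub("\x01$", "", comp))
  })
  df <- if (length(parts)) {
    data.frame(chain = vapply(parts, `[`, "", 1),
               res = vapply(parts, `[`, "", 2),
               atom = vapply(parts, `[`, "", 3),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chain = character(), res = character(), atom = character(),
               stringsAsFactors = FALSE)
  }
  new("ContactSelection", items = df, text = items)
}

#' Resolve a selection against a structure
#'
#' @param selection a \code{\link{ContactSelection-class}} (or expression
#'   string, parsed on the fly).
#' @param structure a \code{\link{PDBStructure-class}}.
#' @return integer vector of matching atom row indices (possibly empty);
#'   the union over selection items.
#' @export
resolveSelection <- function(selection, structure) {
  if (is.character(selection)) selection <- parseSelection(selection)
  a <- structure@atoms
  hits <- integer()
  for (k in seq_len(nrow(selection@items))) {
    it <- selection@items[k, ]
    keep <- rep(TRUE, nrow(a))
    if (nzchar(it$chain)) keep <- keep & a$chain_id == it$chain
    if (nzchar(it$res)) {
      m <- regmatches(it$res, regexec("^(-?[0-9]+)([A-Za-z]?)$", it$res))[[1]]
      if (!length(m)) stop("malformed residue component '", it$res, "'")
      keep <- keep & a$res_seq == as.integer(m[2]) & a$i_code == m[3]
    }
    if (nzchar(it$atom)) keep <- keep & a$name == it$atom
    hits <- union(hits, which(keep))
  }
  sort(hits)
}

# ---------------------------------------------------------------------------
# Entities
# ---------------------------------------------------------------------------

#' Detect molecular entities
#'
#' An entity is either a polymer chain or a connected hetero group (waters
#' excluded): the units between which "inter" interactions are calculated,
#' e.g. a ligand versus its binding site or chain versus chain.
#'
#' @param structure a \code{\link{PDBStructure-class}}.
#' @return list of entities, each a list with \code{id}, \code{kind}
#'   ("polymer_chain" or "hetero_group"), \code{label} and \code{atoms}
#'   (atom row indices).
#' @export
detectEntities <- function(structure) {
  a <- structure@atoms
  r <- structure@residues
  out <- list()
  poly <- r[r$polymer_class %in% c("peptide", "nucleotide"), ]
  for (ch in unique(poly$chain_id)) {
    ridx <- poly$res_index[poly$chain_id == ch]
    out[[length(out) + 1L]] <- list(
      id = length(out) + 1L, kind = "polymer_chain",
      label = paste0("chain ", ch),
      atoms = which(a$res_index %in% ridx))
  }
  het_res <- r$res_index[r$polymer_class == "hetero"]
  het_atoms <- which(a$res_index %in% het_res)
  if (length(het_atoms)) {
    b <- structure@bonds
    keep <- b[, 1] %in% het_atoms & b[, 2] %in% het_atoms
    g <- igraph::make_empty_graph(n = length(het_atoms), directed = FALSE)
    if (any(keep)) {
      e <- cbind(match(b[keep, 1], het_atoms), match(b[keep, 2], het_atoms))
      g <- igraph::add_edges(g, t(e))
    }
    comp <- igraph::components(g)$membership
    for (cid in sort(unique(comp))) {
      members <- het_atoms[comp == cid]
      res_names <- unique(a$res_name[members])
      out[[length(out) + 1L]] <- list(
        id = length(out) + 1L, kind = "hetero_group",
        label = paste(res_names, collapse = "+"),
        atoms = members)
    }
  }
  out
}
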