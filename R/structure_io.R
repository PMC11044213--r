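#' Read a protein structure from PDB or mmCIF
#'
#' Loads the first model of a structure file, keeping polymer (ATOM) residues
#' only: waters and non-polymer heteroatoms are excluded. Alternate locations
#' are resolved per atom to the highest-occupancy record (ties keep the first
#' encountered, i.e. the deposited order).
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (by file extension, default), `"pdb"` or `"cif"`.
#' @return A `fod_structure`: list with `atoms` (data.frame of per-atom
#'   records: `chain`, `resno`, `ins`, `aa`, `elety`, `element`, `x`, `y`,
#'   `z`, `occ`), and `source` metadata.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  at <- parsed$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "DOD", "WAT")), ,
           drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: no polymer residues in ", path)

  atoms <- data.frame(
    chain   = ifelse(is.na(at$chain), " ", at$chain),
    resno   = at$resno,
    ins     = ifelse(is.na(at$insert), "", at$insert),
    aa      = at$resid,
    elety   = at$elety,
    element = atom_element(at),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE)

  # altloc resolution: per (chain, resno, ins, atom name) keep max occupancy,
  # first record on ties; deposited order restored afterwards
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety, sep = "\r")
  ord <- order(match(key, unique(key)), -atoms$occ, seq_along(key))
  keep <- ord[!duplicated(key[ord])]
  atoms <- atoms[sort(keep), , drop = FALSE]
  rownames(atoms) <- NULL

  structure(list(atoms = atoms,
                 source = list(file = path, format = format, model = 1L)),
            class = "fod_structure")
}

# residue key in deposited order
key_of <- function(df) paste(df$chain, df$resno, df$ins, sep = "\r")

# element symbol: use the file's element column when present, else infer
# from the atom name (strip digits, take the leading letter; two-letter
# symbols like FE/ZN never occur in polymer ATOM records we keep)
atom_element <- function(at) {
  el <- if ("elesy" %in% names(at)) toupper(trimws(at$elesy)) else
    rep(NA_character_, nrow(at))
  miss <- is.na(el) | el == ""
  nm <- gsub("[0-9']", "", toupper(at$elety[miss]))
  el[miss] <- substr(nm, 1, 1)
  el
}

#' @export
print.fod_structure <- function(x, ...) {
  a <- x$atoms
  cat("fod_structure:", length(unique(a$chain)), "chain(s),",
      length(unique(key_of(a))), "residues,", nrow(a), "atoms\n")
  cat("  chains:", paste(sort(unique(a$chain)), collapse = " "), "\n")
  cat("  source:", x$source$file, "\n")
  invisible(x)
}

#' Reduce a structure to per-residue effective atoms
#'
#' The effective atom of a residue is the unweighted mean of its heavy-atom
#' coordinates (hydrogens and deuteriums excluded); it is the residue's point
#' representation in every hydrophobicity profile.
#'
#' @param model A `fod_structure` from [read_structure()].
#' @param selection Optional selection string (see [select_residues()]) or
#'   logical/integer index over residues; `NULL` keeps all residues.
#' @return A `fod_residues` data.frame: `chain`, `resno`, `ins`, `aa`,
#'   `x`, `y`, `z` (effective-atom position, Angstrom), `h` (intrinsic
#'   hydrophobicity, `NA` until [assign_hydrophobicity()]).
#' @export
effective_atoms <- function(model, selection = NULL) {
  stopifnot(inherits(model, "fod_structure"))
  a <- model$atoms
  heavy <- !(a$element %in% c("H", "D"))
  a <- a[heavy, , drop = FALSE]
  if (nrow(a) == 0L) stop("no heavy atoms in structure")
  k <- key_of(a)
  uk <- unique(k)
  idx <- match(k, uk)
  first <- match(uk, k)
  res <- data.frame(
    chain = a$chain[first], resno = a$resno[first], ins = a$ins[first],
    aa = a$aa[first],
    x = as.vector(tapply(a$x, idx, mean)),
    y = as.vector(tapply(a$y, idx, mean)),
    z = as.vector(tapply(a$z, idx, mean)),
    h = NA_real_,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("fod_residues", "data.frame")
  if (!is.null(selection)) res <- select_residues(res, selection)
  res
}

#' Select residues with a compact chain/range notation
#'
#' The selection mini-language accepts, optionally prefixed by a structure
#' identifier that is ignored (`"7LUP:Q"` equals `"Q"`):
#' \itemize{
#'   \item `"Q"` - one chain; `"A,C,G"` - several chains;
#'   \item `"A-P"` - an alphabetic chain range (inclusive);
#'   \item `"A:250-461"` - an author-numbering residue range within a chain;
#'   \item `"*"` - every residue.
#' }
#'
#' @param residues A `fod_residues` table (or a `fod_structure`, reduced
#'   first).
#' @param selection Selection string, or a logical/integer vector indexing
#'   residues directly.
#' @return The selected `fod_residues` rows, deposited order preserved.
#' @export
select_residues <- function(residues, selection) {
  if (inherits(residues, "fod_structure")) residues <- effective_atoms(residues)
  if (is.logical(selection) || is.numeric(selection)) {
    out <- residues[selection, , drop = FALSE]
  } else {
    keep <- selection_mask(residues, selection)
    if (!any(keep)) stop("selection '", selection, "' matches no residues")
    out <- residues[keep, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("selection matches no residues")
  rownames(out) <- NULL
  class(out) <- c("fod_residues", "data.frame")
  out
}

selection_mask <- function(residues, spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  spec <- trimws(spec)
  if (spec == "*" || spec == "") return(rep(TRUE, nrow(residues)))
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  range_re <- "^-?[0-9]+--?[0-9]+$|^-?[0-9]+$"
  if (length(parts) == 3L) {
    parts <- parts[-1]                       # drop "<id>:" prefix
  } else if (length(parts) == 2L && !grepl(range_re, parts[2])) {
    parts <- parts[-1]                       # "<id>:<chains>"
  }
  chains <- expand_chains(parts[1])
  keep <- residues$chain %in% chains
  if (length(parts) == 2L) {
    if (!grepl(range_re, parts[2]))
      stop("malformed residue range in selection: ", spec)
    m <- regmatches(parts[2], regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$",
                                      parts[2]))[[1]]
    lo <- as.integer(m[2])
    hi <- if (m[3] == "") lo else as.integer(m[3])
    keep <- keep & residues$resno >= lo & residues$resno <= hi
  }
  keep
}

expand_chains <- function(s) {
  out <- character(0)
  for (tok in strsplit(s, ",", fixed = TRUE)[[1]]) {
    tok <- trimws(tok)
    if (grepl("^[A-Za-z]-[A-Za-z]$", tok)) {
      a <- utf8ToInt(substr(tok, 1, 1)); b <- utf8ToInt(substr(tok, 3, 3))
      out <- c(out, intToUtf8(seq(a, b), multiple = TRUE))
    } else out <- c(out, tok)
  }
  out
}

#' Attach intrinsic hydrophobicities to residues
#'
#' @param records A `fod_residues` table from [effective_atoms()].
#' @param scale A scale name, a [hydrophobicity_scale()] object, or a named
#'   numeric vector over 3-letter codes.
#' @param nonstandard `"error"` (default) rejects residue types not covered
#'   by the scale; `"zero"` assigns them hydrophobicity 0.
#' @return `records` with the `h` column filled; all other fields unchanged.
#' @export
assign_hydrophobicity <- function(records, scale = "kyte_doolittle",
                                  nonstandard = c("error", "zero")) {
  nonstandard <- match.arg(nonstandard)
  sc <- resolve_scale(scale)
  if (all(sc == 0)) stop("degenerate scale: all values are zero")
  h <- unname(unclass(sc)[records$aa])
  if (anyNA(h)) {
    bad <- unique(records$aa[is.na(h)])
    if (nonstandard == "error")
      stop("residue type(s) not covered by scale '", attr(sc, "scale_name"),
           "': ", paste(bad, collapse = ", "))
    h[is.na(h)] <- 0
  }
  records$h <- h
  attr(records, "scale_name") <- attr(sc, "scale_name")
  records
}

#' Define the structural unit a profile describes
#'
#' A unit selection names the residues under analysis and the scope of the
#' Gaussian envelope: `scope = "unit"` fits the envelope to the unit itself;
#' `scope = "complex"` fits it to an enclosing complex and scores the unit
#' as a fragment of the complex-wide profiles.
#'
#' @param members Selection (string or index) for the analysed residues.
#' @param scope `"unit"` or `"complex"`.
#' @param complex_members Selection for the residues spanned by the Gaussian
#'   when `scope = "complex"`; defaults to every residue. Must contain
#'   `members`.
#' @return A `unit_selection` object.
#' @export
unit_selection <- function(members, scope = c("unit", "complex"),
                           complex_members = "*") {
  scope <- match.arg(scope)
  structure(list(members = members, scope = scope,
                 complex_members = complex_members),
            class = "unit_selection")
}
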