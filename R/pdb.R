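# PDB coordinate input under the ensemble policies: only ATOM records, only
# the first MODEL, first alternate location wins, chain selection by
# autodetection ("first"), wildcard ("*"), blank id ("_") or an explicit
# chain character.  Fixed-column parsing per the PDB 3.3 format.

AA_3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA_1TO3 <- structure(names(AA_3TO1), names = unname(AA_3TO1))

#' Read a protein structure from a PDB file
#'
#' Parses standard `ATOM` records (fixed columns).  `HETATM` records are
#' ignored.  When the file contains several models (NMR ensembles), only the
#' first model is read.  When an atom has alternate locations, only the
#' first one encountered in the file is kept.
#'
#' @param path path to a PDB file.
#' @param chain_spec chain selection: `"first"` (default) keeps the chain of
#'   the first `ATOM` record, `"*"` keeps all chains, `"_"` selects records
#'   with a blank chain identifier, and any other single character selects
#'   that chain exactly.
#' @param label structure label; defaults to the file basename without
#'   extension.
#' @param family optional family label carried through to statistics.
#' @return an object of class `pdb_structure`: a list with `label`,
#'   `chain_spec`, `chains_used`, `family`, an `atoms` data frame (one row
#'   per atom: `name`, `element`, `x`, `y`, `z`, `occ`, `b`, `altloc`,
#'   `chain`, `resno`, `icode`, `resid`, `ridx`) and a `residues` data frame
#'   (one row per residue in order: `chain`, `resno`, `icode`, `resid`).
#' @export
read_pdb <- function(path, chain_spec = "first", label = NULL, family = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  pdb_structure_from_lines(lines, chain_spec = chain_spec, label = label,
                           family = family, source = path)
}

pdb_structure_from_lines <- function(lines, chain_spec = "first",
                                     label = "structure", family = NULL,
                                     source = "<text>") {
  rectype <- trimws(substr(lines, 1L, 6L))
  # restrict to the first model when MODEL records are present
  imodel <- which(rectype == "MODEL")
  if (length(imodel)) {
    iend <- which(rectype == "ENDMDL")
    last <- if (length(iend)) iend[1L] else length(lines)
    keep <- seq(imodel[1L], last)
    lines <- lines[keep]
    rectype <- rectype[keep]
  }
  atom_lines <- lines[rectype == "ATOM"]
  if (!length(atom_lines)) stop("no ATOM records in ", source)

  short <- nchar(atom_lines) < 66L
  if (any(short)) {
    warning(sum(short), " ATOM record(s) in ", source,
            " end before the B-factor column; b_factor set to 0")
    atom_lines <- formatC(atom_lines, width = -66L)  # right-pad with spaces
  }
  fld <- function(from, to) substr(atom_lines, from, to)
  num <- function(x) suppressWarnings(as.numeric(x))
  atoms <- data.frame(
    name = trimws(fld(13L, 16L)),
    element = trimws(fld(77L, 78L)),
    x = num(fld(31L, 38L)), y = num(fld(39L, 46L)), z = num(fld(47L, 54L)),
    occ = num(fld(55L, 60L)), b = num(fld(61L, 66L)),
    altloc = trimws(fld(17L, 17L)),
    chain = trimws(fld(22L, 22L)),
    resno = as.integer(trimws(fld(23L, 26L))),
    icode = trimws(fld(27L, 27L)),
    resid = toupper(trimws(fld(18L, 20L))),
    stringsAsFactors = FALSE)
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) || anyNA(atoms$resno))
    stop("malformed ATOM record in ", source)

  # chain selection
  chains_present <- unique(atoms$chain)
  keep <- switch(chain_spec,
                 "first" = atoms$chain == atoms$chain[1L],
                 "*" = rep(TRUE, nrow(atoms)),
                 "_" = atoms$chain == "",
                 atoms$chain == chain_spec)
  if (!any(keep))
    stop("chain spec '", chain_spec, "' matches no chain in ", source,
         " (chains present: ",
         paste(ifelse(chains_present == "", "_", chains_present),
               collapse = ", "), ")")
  atoms <- atoms[keep, , drop = FALSE]

  # first altloc wins: drop later duplicates of the same atom name in the
  # same residue (file order)
  akey <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "\r")
  atoms <- atoms[!duplicated(akey), , drop = FALSE]

  # residue ordering: chain order of appearance, then residue number, then
  # insertion code (blank before lettered)
  chain_order <- unique(atoms$chain)
  rkey <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  rfirst <- !duplicated(rkey)
  residues <- data.frame(chain = atoms$chain[rfirst],
                         resno = atoms$resno[rfirst],
                         icode = atoms$icode[rfirst],
                         resid = atoms$resid[rfirst],
                         stringsAsFactors = FALSE)
  ord <- order(match(residues$chain, chain_order), residues$resno,
               residues$icode)
  residues <- residues[ord, , drop = FALSE]
  rownames(residues) <- NULL
  atoms$ridx <- match(rkey, paste(residues$chain, residues$resno,
                                  residues$icode, sep = "\r"))
  atoms <- atoms[order(atoms$ridx), , drop = FALSE]
  rownames(atoms) <- NULL

  structure(list(label = label, chain_spec = chain_spec,
                 chains_used = chain_order, family = family,
                 atoms = atoms, residues = residues),
            class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat("<pdb_structure> ", x$label, ": ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " atoms, chain(s) ",
      paste(ifelse(x$chains_used == "", "_", x$chains_used), collapse = ","),
      if (!is.null(x$family)) paste0(", family ", x$family), "\n", sep = "")
  invisible(x)
}

#' Write a structure as PDB ATOM records
#'
#' Emits standard fixed-column `ATOM` records (plus a final `TER`/`END`)
#' for the residues of a `pdb_structure`.  Together with [read_pdb()] this
#' round-trips the supported record subset.
#'
#' @param s a `pdb_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "pdb_structure"))
  a <- s$atoms
  name4 <- ifelse(nchar(a$name) >= 4L, a$name, sprintf(" %-3s", a$name))
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000L, name4, substr(a$altloc, 1L, 1L),
    a$resid, ifelse(a$chain == "", " ", a$chain), a$resno,
    ifelse(a$icode == "", " ", a$icode),
    a$x, a$y, a$z, a$occ, a$b, a$element)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' One-letter amino-acid sequence of a structure
#'
#' Standard residues map to their one-letter codes; any other residue name
#' (e.g. MSE) maps to `"X"`.
#'
#' @param s a `pdb_structure`.
#' @return a list with `sequence` (single string) and `residues` (integer
#'   indices into `s$residues`, parallel to the sequence characters).
#' @export
extract_sequence <- function(s) {
  stopifnot(inherits(s, "pdb_structure"))
  if (nrow(s$residues) == 0L) stop("empty structure")
  letters1 <- AA_3TO1[s$residues$resid]
  letters1[is.na(letters1)] <- "X"
  list(sequence = paste(letters1, collapse = ""),
       residues = seq_len(nrow(s$residues)))
}

#' Parse a Structure list
#'
#' One entry per non-blank, non-comment (`#`) line: a PDB file basename, an
#' optional chain spec (defaults to `"first"`; `"_"` requests the blank
#' chain id) and an optional family label.
#'
#' @param text the list as a single string or character vector of lines.
#' @return a data frame with columns `basename`, `chain`, `family`
#'   (`NA` when absent).
#' @export
parse_structure_list <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  content <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(content)))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(content[i]), "[ \t]+")[[1L]]
    if (length(f) > 3L)
      stop("Structure list line ", i, " has ", length(f),
           " fields (at most 3 allowed): ", trimws(lines[i]))
    data.frame(basename = f[1L],
               chain = if (length(f) >= 2L) f[2L] else "first",
               family = if (length(f) >= 3L) f[3L] else NA_character_,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(basename = character(), chain = character(),
                      family = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parse a Position list
#'
#' Whitespace-separated tokens over any number of lines: inclusive
#' alignment-position ranges (`144-166`), single positions (`150`) and
#' dihedral-angle names (`phi`, `psi`, `omega`, `chi1`..`chi4`).  Comment
#' lines start with `#`.  When no angle token is given the angle set
#' defaults to phi and psi; when no range is given all positions are
#' selected (`ranges = NULL`).
#'
#' @param text the list as a single string or character vector of lines;
#'   `NULL` or empty means no restriction.
#' @return a `position_selection`: list with `ranges` (two-column integer
#'   matrix of inclusive intervals, or `NULL` for all positions) and
#'   `angles` (character vector).
#' @export
parse_position_list <- function(text = NULL) {
  if (is.null(text)) text <- character()
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  content <- sub("#.*$", "", lines)
  tokens <- unlist(strsplit(trimws(content[nzchar(trimws(content))]), "[ \t]+"))
  ranges <- NULL
  angles <- character()
  for (tk in tokens) {
    if (tk %in% ANGLE_NAMES) {
      angles <- union(angles, tk)
    } else if (grepl("^-?[0-9]+$", tk)) {
      p <- as.integer(tk)
      ranges <- rbind(ranges, c(p, p))
    } else if (grepl("^-?[0-9]+--?[0-9]+$", tk)) {
      m <- regmatches(tk, regexec("^(-?[0-9]+)-(-?[0-9]+)$", tk))[[1L]]
      lo <- as.integer(m[2L]); hi <- as.integer(m[3L])
      if (hi < lo) stop("inverted position range: ", tk)
      ranges <- rbind(ranges, c(lo, hi))
    } else {
      stop("unrecognized Position list token: ", tk)
    }
  }
  if (!length(angles)) angles <- c("phi", "psi")
  structure(list(ranges = ranges, angles = angles),
            class = "position_selection")
}

# expand a selection's ranges to the explicit position set
selection_positions <- function(selection) {
  if (is.null(selection$ranges)) return(NULL)
  unique(unlist(apply(selection$ranges, 1L, function(r) seq(r[1L], r[2L]),
                      simplify = FALSE)))
}
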