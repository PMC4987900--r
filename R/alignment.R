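# Residue <-> alignment-position correspondence.  Two routes: derive the
# alignment from consistent PDB residue numbering, or ingest a pre-computed
# multiple sequence alignment (aligned FASTA or CLUSTAL) and validate it
# against the structures' extracted sequences.

new_alignment <- function(labels, cells, first_position = 1L) {
  stopifnot(is.matrix(cells), nrow(cells) == length(labels))
  rownames(cells) <- labels
  structure(list(labels = labels, cells = cells, n_columns = ncol(cells),
                 first_position = as.integer(first_position)),
            class = "ensemble_alignment")
}

#' @export
print.ensemble_alignment <- function(x, ...) {
  cat("<ensemble_alignment> ", length(x$labels), " structures x ",
      x$n_columns, " positions (", x$first_position, "..",
      x$first_position + x$n_columns - 1L, ")\n", sep = "")
  invisible(x)
}

alignment_positions <- function(a) {
  a$first_position + seq_len(a$n_columns) - 1L
}

#' Alignment from consistent residue numbering
#'
#' Builds the residue correspondence assuming residues are numbered
#' consistently across structures: the columns are the sorted union of
#' residue keys (residue number and insertion code; the chain id joins the
#' key when any structure carries several chains), and each structure's
#' cell at a column is its residue with that key, or a gap.
#'
#' @param structures list of `pdb_structure` objects.
#' @return an `ensemble_alignment`: structure labels, an integer cell
#'   matrix (structures x columns) holding residue indices with `NA` for
#'   gaps, and the first position number (1 by default; see [renumber()]).
#' @export
align_by_numbering <- function(structures) {
  stopifnot(length(structures) >= 1L)
  labels <- vapply(structures, function(s) s$label, character(1L))
  if (anyDuplicated(labels))
    stop("duplicate structure labels: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  multi <- any(vapply(structures,
                      function(s) length(unique(s$residues$chain)) > 1L,
                      logical(1L)))
  keys <- lapply(structures, function(s) {
    r <- s$residues
    if (multi) paste(r$chain, r$resno, r$icode, sep = "\r")
    else paste(r$resno, r$icode, sep = "\r")
  })
  for (i in seq_along(keys)) {
    if (anyDuplicated(keys[[i]]))
      stop("structure ", labels[i],
           " has duplicate residue numbering; numbering-based alignment ",
           "requires consistent, unique residue numbers")
  }
  keydf <- do.call(rbind, lapply(structures, function(s) {
    r <- s$residues
    data.frame(chain = r$chain, resno = r$resno, icode = r$icode,
               stringsAsFactors = FALSE)
  }))
  allkeys <- unique(do.call(paste, c(as.list(
    if (multi) keydf[c("chain", "resno", "icode")]
    else keydf[c("resno", "icode")]), sep = "\r")))
  kd <- keydf[match(allkeys, do.call(paste, c(as.list(
    if (multi) keydf[c("chain", "resno", "icode")]
    else keydf[c("resno", "icode")]), sep = "\r"))), , drop = FALSE]
  ord <- if (multi) order(kd$chain, kd$resno, kd$icode)
  else order(kd$resno, kd$icode)
  allkeys <- allkeys[ord]
  cells <- do.call(rbind, lapply(seq_along(structures), function(i) {
    match(allkeys, keys[[i]])
  }))
  new_alignment(labels, cells)
}

#' Read a user-supplied multiple sequence alignment
#'
#' Reads an aligned FASTA or CLUSTAL file and binds its rows to structures.
#' Rows are matched by label: the structure label, optionally suffixed with
#' `:<chain>` when an explicit chain was requested.  Each row, with gaps
#' removed, must reproduce the structure's extracted sequence exactly.
#'
#' @param path path to the alignment file; format is auto-detected
#'   (CLUSTAL header vs FASTA `>`).
#' @param structures list of `pdb_structure` objects, one per row.
#' @return an `ensemble_alignment` (structure order follows `structures`).
#' @export
read_alignment <- function(path, structures) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  first <- trimws(readLines(path, n = 50L, warn = FALSE))
  first <- first[nzchar(first)]
  if (!length(first)) stop("empty alignment file: ", path)
  if (grepl("^CLUSTAL", first[1L], ignore.case = TRUE)) {
    rows <- read_clustal_rows(path)
  } else if (startsWith(first[1L], ">")) {
    aln <- seqinr::read.alignment(path, format = "fasta",
                                  forceToLower = FALSE)
    rows <- unlist(aln$seq)
    names(rows) <- vapply(strsplit(aln$nam, "[ \t]"), `[[`,
                          character(1L), 1L)
  } else {
    stop("unrecognized alignment format in ", path,
         " (expected aligned FASTA or CLUSTAL)")
  }
  rows <- toupper(gsub("\\.", "-", rows))
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows have unequal lengths in ", path)
  bind_alignment_rows(rows, structures)
}

# Block-wise CLUSTAL parser: "name  sequence [count]" lines, grouped in
# blocks; header, blank and conservation-symbol lines are skipped.
read_clustal_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)[-1L]
  rows <- character(); order_seen <- character()
  for (ln in lines) {
    if (!nzchar(trimws(ln)) || grepl("^\\s", ln)) next
    f <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (length(f) < 2L) next
    nm <- f[1L]
    seqpart <- f[2L]
    if (!grepl("^[A-Za-z.\\-]+$", seqpart))
      stop("malformed CLUSTAL sequence line: ", ln)
    if (!nm %in% order_seen) {
      order_seen <- c(order_seen, nm)
      rows[nm] <- seqpart
    } else {
      rows[nm] <- paste0(rows[nm], seqpart)
    }
  }
  if (!length(rows)) stop("no sequence rows found in CLUSTAL file ", path)
  rows
}

bind_alignment_rows <- function(rows, structures) {
  labels <- vapply(structures, function(s) s$label, character(1L))
  n_col <- nchar(rows[[1L]])
  cells <- matrix(NA_integer_, nrow = length(structures), ncol = n_col)
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    cand <- c(s$label,
              if (!s$chain_spec %in% c("first", "*", "_"))
                paste0(s$label, ":", s$chain_spec))
    hit <- cand[cand %in% names(rows)]
    if (!length(hit))
      stop("no alignment row matches structure '", s$label,
           "' (rows present: ", paste(names(rows), collapse = ", "), ")")
    row <- strsplit(rows[[hit[1L]]], "")[[1L]]
    isres <- row != "-"
    seq1 <- strsplit(extract_sequence(s)$sequence, "")[[1L]]
    if (sum(isres) != length(seq1))
      stop("alignment row for '", s$label, "' has ", sum(isres),
           " residues but the structure has ", length(seq1))
    mism <- which(row[isres] != seq1)
    if (length(mism))
      stop("alignment row for '", s$label, "' disagrees with the structure ",
           "sequence at residue offset ", mism[1L], " ('",
           row[isres][mism[1L]], "' vs '", seq1[mism[1L]], "')")
    cells[i, isres] <- seq_len(length(seq1))
  }
  new_alignment(labels, cells)
}

#' Shift alignment position numbering
#'
#' Only the reported position numbers change; the residue correspondence is
#' untouched.  Positions are numbered starting from 1 by default.
#'
#' @param a an `ensemble_alignment`.
#' @param first_position position number of the first column.
#' @return the renumbered alignment.
#' @export
renumber <- function(a, first_position) {
  stopifnot(inherits(a, "ensemble_alignment"))
  a$first_position <- as.integer(first_position)
  a
}

#' Residues of one alignment column
#'
#' @param a an `ensemble_alignment`.
#' @param position a position number within the alignment's current
#'   numbering.
#' @return a data frame with one row per structure (in structure order):
#'   `label` and `residue` (index into that structure's residue table, `NA`
#'   for a gap).
#' @export
column_residues <- function(a, position) {
  stopifnot(inherits(a, "ensemble_alignment"))
  col <- position - a$first_position + 1L
  if (col < 1L || col > a$n_columns)
    stop("position ", position, " outside the alignment (",
         a$first_position, "..", a$first_position + a$n_columns - 1L, ")")
  data.frame(label = a$labels, residue = a$cells[, col],
             stringsAsFactors = FALSE)
}

# aligned one-letter rows (with "-" gaps), e.g. for FASTA output
alignment_rows <- function(a, structures) {
  vapply(seq_along(a$labels), function(i) {
    s <- structures[[i]]
    seq1 <- strsplit(extract_sequence(s)$sequence, "")[[1L]]
    row <- rep("-", a$n_columns)
    filled <- !is.na(a$cells[i, ])
    row[filled] <- seq1[a$cells[i, filled]]
    paste(row, collapse = "")
  }, character(1L))
}
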