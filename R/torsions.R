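# Backbone (phi, psi, omega) and sidechain (chi1-chi4) torsion angles with
# explicit undefined semantics: phi does not exist at the N-terminal side of
# a stretch of contiguous residues, psi and omega at the C-terminal side,
# and any missing atom makes the corresponding angle undefined (NA).

ANGLE_NAMES <- c("phi", "psi", "omega", "chi1", "chi2", "chi3", "chi4")

# peptide-bond contiguity cutoff: residues i and i+1 are contiguous iff
# the C(i)-N(i+1) distance is below this (Angstrom)
PEPTIDE_BOND_CUTOFF <- 2.5

# Normative chi atom quadruples.  Each entry lists, per chi, the four atom
# names; the k-th chi of a residue type exists iff listed here.  Raw values
# are reported: no folding of 2-fold-degenerate terminal dihedrals
# (Phe/Tyr chi2, Asp chi2, Glu chi3).
CHI_ATOMS <- list(
  ARG = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  LYS = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  GLU = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  ASP = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "OD1")),
  HIS = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD1")),
  PHE = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  ALA = list(),
  GLY = list())

# coordinates of a named atom in residue ridx, or NULL if absent
atom_xyz <- function(s, ridx, name) {
  i <- which(s$atoms$ridx == ridx & s$atoms$name == name)
  if (!length(i)) return(NULL)
  c(s$atoms$x[i[1L]], s$atoms$y[i[1L]], s$atoms$z[i[1L]])
}

safe_torsion <- function(p1, p2, p3, p4) {
  if (is.null(p1) || is.null(p2) || is.null(p3) || is.null(p4))
    return(NA_real_)
  torsion_angle(p1, p2, p3, p4)
}

# residues i, i+1 contiguous: same chain and peptide C-N distance < cutoff
contiguous_next <- function(s) {
  n <- nrow(s$residues)
  out <- logical(max(n - 1L, 0L))
  for (i in seq_len(n - 1L)) {
    if (s$residues$chain[i] != s$residues$chain[i + 1L]) next
    cc <- atom_xyz(s, i, "C")
    nn <- atom_xyz(s, i + 1L, "N")
    out[i] <- !is.null(cc) && !is.null(nn) &&
      vnorm(nn - cc) < PEPTIDE_BOND_CUTOFF
  }
  out
}

# n_residues x 7 matrix of torsion values (NA = undefined)
torsion_matrix <- function(s) {
  stopifnot(inherits(s, "pdb_structure"))
  n <- nrow(s$residues)
  m <- matrix(NA_real_, nrow = n, ncol = length(ANGLE_NAMES),
              dimnames = list(NULL, ANGLE_NAMES))
  if (n == 0L) return(m)
  contig <- contiguous_next(s)
  for (i in seq_len(n)) {
    N <- atom_xyz(s, i, "N"); CA <- atom_xyz(s, i, "CA")
    C <- atom_xyz(s, i, "C")
    if (i > 1L && contig[i - 1L])
      m[i, "phi"] <- safe_torsion(atom_xyz(s, i - 1L, "C"), N, CA, C)
    if (i < n && contig[i]) {
      N1 <- atom_xyz(s, i + 1L, "N")
      m[i, "psi"] <- safe_torsion(N, CA, C, N1)
      m[i, "omega"] <- safe_torsion(CA, C, N1, atom_xyz(s, i + 1L, "CA"))
    }
    quads <- CHI_ATOMS[[s$residues$resid[i]]]
    if (!is.null(quads)) {
      for (k in seq_along(quads)) {
        q <- quads[[k]]
        m[i, k + 3L] <- safe_torsion(atom_xyz(s, i, q[1L]),
                                     atom_xyz(s, i, q[2L]),
                                     atom_xyz(s, i, q[3L]),
                                     atom_xyz(s, i, q[4L]))
      }
    }
  }
  m
}

#' Backbone torsion angles of a structure
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1);
#' omega(i) = CA(i)-C(i)-N(i+1)-CA(i+1), attributed to residue i.  An angle
#' is defined only when the neighbouring residue is contiguous (peptide
#' C-N distance below 2.5 Angstrom, same chain) and all four atoms exist;
#' otherwise the value is `NA`.
#'
#' @param s a `pdb_structure`.
#' @return a long data frame: `label`, `chain`, `resno`, `icode`, `resid`,
#'   `residue` (index), `angle`, `value` (degrees in (-180, 180], `NA` when
#'   undefined).
#' @export
backbone_torsions <- function(s) {
  torsion_long(s, c("phi", "psi", "omega"))
}

#' Sidechain torsion angles of a structure
#'
#' chi1-chi4 following the standard heavy-atom quadruples (chi1 ends at CG,
#' or CG1/OG/OG1/SG depending on residue type; Pro has chi1 and chi2 only).
#' Residues lacking a given chi (Ala, Gly) or missing atoms yield `NA`.
#'
#' @inheritParams backbone_torsions
#' @return a long data frame as in [backbone_torsions()].
#' @export
sidechain_torsions <- function(s) {
  torsion_long(s, c("chi1", "chi2", "chi3", "chi4"))
}

torsion_long <- function(s, angles) {
  m <- torsion_matrix(s)[, angles, drop = FALSE]
  n <- nrow(s$residues)
  data.frame(label = s$label,
             chain = rep(s$residues$chain, times = length(angles)),
             resno = rep(s$residues$resno, times = length(angles)),
             icode = rep(s$residues$icode, times = length(angles)),
             resid = rep(s$residues$resid, times = length(angles)),
             residue = rep(seq_len(n), times = length(angles)),
             angle = rep(angles, each = n),
             value = as.vector(m),
             stringsAsFactors = FALSE)
}

#' Torsion table for an ensemble
#'
#' Backbone and sidechain torsions of every structure, in one long table.
#'
#' @param structures list of `pdb_structure` objects (or a `superposition`;
#'   torsions are internal coordinates, unaffected by superposition).
#' @return a long data frame as in [backbone_torsions()], all seven angle
#'   types, all structures.
#' @export
ensemble_torsions <- function(structures) {
  structures <- as_structure_list(structures)
  out <- do.call(rbind, lapply(structures, function(s)
    torsion_long(s, ANGLE_NAMES)))
  rownames(out) <- NULL
  out
}

as_structure_list <- function(x) {
  if (inherits(x, "superposition")) return(x$structures)
  if (inherits(x, "pdb_structure")) return(list(x))
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1L), "pdb_structure")))
  x
}
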