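# Synthetic structure builder: idealized-geometry peptide chains placed
# sequentially from target torsions (NeRF-style internal-to-Cartesian
# construction).  Built chains round-trip: recomputing torsions on the
# result reproduces the targets.  Fixtures, not physical models: fixed
# bond lengths/angles, no sterics.

# idealized backbone geometry (Angstrom / degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
ANGLE_N_CA_C <- 111.0
ANGLE_CA_C_N <- 117.0
ANGLE_C_N_CA <- 121.0
ANGLE_CA_C_O <- 120.8

# sidechain bond length by leading element of the placed atom
sidechain_bond <- function(atom_name) {
  switch(substr(atom_name, 1L, 1L),
         O = 1.43, S = 1.81, N = 1.47, 1.52)
}
SIDECHAIN_ANGLE <- 111.0

element_of <- function(name) substr(name, 1L, 1L)

#' Build a synthetic peptide chain from target torsions
#'
#' Places backbone atoms (N, CA, C, O) residue by residue with idealized
#' bond lengths and angles so that the backbone torsions equal the targets,
#' then grows sidechain atoms along the chi1-chi4 chains (through CB) so
#' that the sidechain torsions equal their targets.  Recomputing torsions
#' on the built structure reproduces every target to numerical precision.
#'
#' @param sequence one-letter amino-acid string (standard 20 letters).
#' @param phi,psi,omega backbone torsion targets in degrees; scalars
#'   recycle over the chain.  phi of the first residue and psi/omega of the
#'   last are geometrically unused.
#' @param chi optional list (one element per residue) of numeric chi
#'   targets in degrees; `NULL` entries get 180 for every chi the residue
#'   type supports.
#' @param resno_start first residue number.
#' @param chain chain identifier.
#' @param label structure label.
#' @param family optional family label.
#' @param b_factor B-factor written on every atom.
#' @param break_after integer residue indices i after which the peptide
#'   C(i)-N(i+1) bond is stretched to 4 Angstrom, engineering a chain
#'   break that violates the contiguity cutoff.
#' @return a `pdb_structure`.
#' @export
build_chain <- function(sequence, phi = -57, psi = -47, omega = 180,
                        chi = NULL, resno_start = 1L, chain = "A",
                        label = "synthetic", family = NULL, b_factor = 0,
                        break_after = integer()) {
  letters1 <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(letters1)
  if (n < 1L) stop("empty sequence")
  res3 <- AA_1TO3[letters1]
  if (anyNA(res3))
    stop("invalid residue letter(s): ",
         paste(unique(letters1[is.na(res3)]), collapse = ", "))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  if (is.null(chi)) chi <- vector("list", n)
  stopifnot(length(chi) == n)

  coords <- list()  # coords[[i]][[atom_name]] = 3-vector
  for (i in seq_len(n)) coords[[i]] <- list()

  # first residue: N at origin, CA on x, C in the xy-plane
  coords[[1L]][["N"]] <- c(0, 0, 0)
  coords[[1L]][["CA"]] <- c(BOND_N_CA, 0, 0)
  th <- deg2rad(180 - ANGLE_N_CA_C)
  coords[[1L]][["C"]] <- coords[[1L]][["CA"]] +
    BOND_CA_C * c(cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    N <- coords[[i]][["N"]]; CA <- coords[[i]][["CA"]]
    C <- coords[[i]][["C"]]
    if (i < n) {
      bond_cn <- if (i %in% break_after) 4.0 else BOND_C_N
      coords[[i + 1L]][["N"]] <- as.vector(
        place_atom(N, CA, C, bond_cn, ANGLE_CA_C_N, psi[i]))
      coords[[i + 1L]][["CA"]] <- as.vector(
        place_atom(CA, C, coords[[i + 1L]][["N"]], BOND_N_CA,
                   ANGLE_C_N_CA, omega[i]))
      coords[[i + 1L]][["C"]] <- as.vector(
        place_atom(C, coords[[i + 1L]][["N"]], coords[[i + 1L]][["CA"]],
                   BOND_CA_C, ANGLE_N_CA_C, phi[i + 1L]))
    }
    # carbonyl O: torsion N-CA-C-O = psi + 180 (trans to the next N)
    coords[[i]][["O"]] <- as.vector(
      place_atom(N, CA, C, BOND_C_O, ANGLE_CA_C_O,
                 wrap_angle(psi[i] + 180)))
    # sidechain: CB off CA in the N/C frame, then along the chi chain
    if (res3[i] != "GLY") {
      coords[[i]][["CB"]] <- as.vector(
        place_atom(C, N, CA, 1.53, 110.5, -120))
      quads <- CHI_ATOMS[[res3[i]]]
      chis <- rep_len(if (is.null(chi[[i]])) 180 else chi[[i]],
                      length(quads))
      for (k in seq_along(quads)) {
        q <- quads[[k]]
        coords[[i]][[q[4L]]] <- as.vector(
          place_atom(coords[[i]][[q[1L]]], coords[[i]][[q[2L]]],
                     coords[[i]][[q[3L]]], sidechain_bond(q[4L]),
                     SIDECHAIN_ANGLE, chis[k]))
      }
    }
  }

  rows <- list()
  for (i in seq_len(n)) {
    for (nm in names(coords[[i]])) {
      p <- coords[[i]][[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, element = element_of(nm), x = p[1L], y = p[2L], z = p[3L],
        occ = 1, b = b_factor, altloc = "", chain = chain,
        resno = resno_start + i - 1L, icode = "", resid = res3[i],
        ridx = i, stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  residues <- data.frame(chain = chain,
                         resno = resno_start + seq_len(n) - 1L,
                         icode = "", resid = unname(res3),
                         stringsAsFactors = FALSE)
  structure(list(label = label, chain_spec = chain, chains_used = chain,
                 family = family, atoms = atoms, residues = residues),
            class = "pdb_structure")
}

#' Build a synthetic conformational ensemble
#'
#' Generates `n` structures per family from a base chain: each structure's
#' backbone torsions are the base targets plus the family's offsets plus
#' wrapped-normal noise of standard deviation `perturbation_sd`, applied in
#' torsion space (where the clustering metric lives).  Reproducible for a
#' fixed seed.
#'
#' @inheritParams build_chain
#' @param n structures per family (or total when `families` is `NULL`).
#' @param families optional list of families, each a list with `label` and
#'   offset vectors/scalars `dphi`, `dpsi` (degrees) added to the base
#'   targets.  `NULL` means one unnamed family with zero offsets.
#' @param perturbation_sd wrapped-normal noise sd in degrees (>= 0).
#' @param seed RNG seed.
#' @param label_prefix structure labels are
#'   `<prefix><two-digit index>`.
#' @return a list with `structures`, `entries` (Structure list data
#'   frame), `structure_list` (its text form) and `families` (named vector
#'   label -> family, or `NULL`).
#' @export
build_ensemble <- function(sequence, n = 1L, phi = -57, psi = -47,
                           omega = 180, chi = NULL, families = NULL,
                           perturbation_sd = 0, seed = 1L, chain = "A",
                           label_prefix = "synth", b_factor = 0) {
  stopifnot(n >= 1L, perturbation_sd >= 0)
  set.seed(seed)
  nres <- nchar(sequence)
  phi <- rep_len(phi, nres); psi <- rep_len(psi, nres)
  fams <- if (is.null(families)) list(list(label = NA_character_,
                                           dphi = 0, dpsi = 0))
  else families
  structures <- list()
  entry_rows <- list()
  k <- 0L
  for (f in fams) {
    fphi <- phi + rep_len(f$dphi, nres)
    fpsi <- psi + rep_len(f$dpsi, nres)
    for (j in seq_len(n)) {
      k <- k + 1L
      lab <- sprintf("%s%02d", label_prefix, k)
      sphi <- wrap_angle(fphi + stats::rnorm(nres, 0, perturbation_sd))
      spsi <- wrap_angle(fpsi + stats::rnorm(nres, 0, perturbation_sd))
      structures[[k]] <- build_chain(sequence, phi = sphi, psi = spsi,
                                     omega = omega, chi = chi,
                                     chain = chain, label = lab,
                                     family = if (is.na(f$label)) NULL
                                     else f$label,
                                     b_factor = b_factor)
      entry_rows[[k]] <- data.frame(basename = lab, chain = chain,
                                    family = f$label,
                                    stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, entry_rows)
  text <- paste(entries$basename, entries$chain,
                ifelse(is.na(entries$family), "", entries$family))
  text <- trimws(text, which = "right")
  fam_vec <- if (all(is.na(entries$family))) NULL
  else structure(entries$family, names = entries$basename)
  list(structures = structures, entries = entries,
       structure_list = paste(text, collapse = "\n"), families = fam_vec)
}

#' Write an ensemble's PDB files and Structure list to a directory
#'
#' @param ensemble result of [build_ensemble()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in ensemble$structures)
    write_pdb(s, file.path(dir, paste0(s$label, ".pdb")))
  writeLines(ensemble$structure_list, file.path(dir, "structures.txt"))
  invisible(dir)
}
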