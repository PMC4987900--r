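# Per-alignment-position Cartesian fluctuations and average B-factors for
# backbone and sidechain atom groups, computed on a superposed ensemble.

# heavy-atom group membership: backbone = N, CA, C, O; sidechain = all
# other heavy atoms; OXT belongs to neither; hydrogens are excluded
atom_group <- function(name, element) {
  is_h <- element == "H" | grepl("^[0-9]*H", name)
  ifelse(is_h | name == "OXT", NA_character_,
         ifelse(name %in% BACKBONE_ATOMS, "backbone", "sidechain"))
}

# all (structure, atom) records of one group at one alignment column
position_group_atoms <- function(structures, cells, col, group) {
  recs <- lapply(seq_along(structures), function(i) {
    ridx <- cells[i, col]
    if (is.na(ridx)) return(NULL)
    a <- structures[[i]]$atoms
    sel <- which(a$ridx == ridx & atom_group(a$name, a$element) %in% group)
    if (!length(sel)) return(NULL)
    data.frame(struct = i, name = a$name[sel], x = a$x[sel], y = a$y[sel],
               z = a$z[sel], b = a$b[sel], stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Cartesian fluctuation at one alignment position
#'
#' For each atom name of the group present in at least two structures at
#' the position, the per-atom fluctuation is the population root mean
#' square deviation from the ensemble-mean position,
#' \eqn{f_a = \sqrt{\frac{1}{N_a}\sum_s |r_{s,a} - \bar r_a|^2}}; the
#' position's fluctuation RMS-combines the contributing atoms,
#' \eqn{\sqrt{\mathrm{mean}_a f_a^2}}.  The mean B-factor averages over all
#' (structure, atom) pairs of the group, including atoms present in only
#' one structure.  Positions where the group is empty (e.g. sidechain at a
#' Gly-only position) report fluctuation 0 and mean B 0.
#'
#' @param structures a `superposition` or list of already superposed
#'   `pdb_structure` objects.
#' @param alignment the `ensemble_alignment`.
#' @param position alignment position number.
#' @param group `"backbone"` or `"sidechain"`.
#' @return a one-row data frame: `position`, `group`, `fluctuation`
#'   (Angstrom), `mean_b`, `n_structures` (structures contributing any
#'   group atom), `n_atoms` (distinct atom names entering the
#'   fluctuation).
#' @export
cartesian_fluctuation <- function(structures, alignment, position,
                                  group = c("backbone", "sidechain")) {
  group <- match.arg(group)
  structures <- as_structure_list(structures)
  col <- position - alignment$first_position + 1L
  if (col < 1L || col > alignment$n_columns)
    stop("position ", position, " outside the alignment")
  recs <- position_group_atoms(structures, alignment$cells, col, group)
  if (is.null(recs) || nrow(recs) == 0L)
    return(data.frame(position = position, group = group, fluctuation = 0,
                      mean_b = 0, n_structures = 0L, n_atoms = 0L,
                      stringsAsFactors = FALSE))
  f2 <- c()
  for (nm in unique(recs$name)) {
    sub <- recs[recs$name == nm, , drop = FALSE]
    if (nrow(sub) < 2L) next  # single-structure atoms: B only
    xyz <- as.matrix(sub[, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    f2[nm] <- mean(rowSums(sweep(xyz, 2L, ctr)^2))
  }
  data.frame(position = position, group = group,
             fluctuation = if (length(f2)) sqrt(mean(f2)) else 0,
             mean_b = mean(recs$b),
             n_structures = length(unique(recs$struct)),
             n_atoms = length(f2), stringsAsFactors = FALSE)
}

#' Cartesian statistics table for the whole alignment
#'
#' [cartesian_fluctuation()] evaluated at every alignment position for both
#' atom groups; rows ordered by position, backbone before sidechain.
#'
#' @inheritParams cartesian_fluctuation
#' @return a data frame with one row per (position, group).
#' @export
cartesian_table <- function(structures, alignment) {
  structures <- as_structure_list(structures)
  rows <- lapply(alignment_positions(alignment), function(p)
    rbind(cartesian_fluctuation(structures, alignment, p, "backbone"),
          cartesian_fluctuation(structures, alignment, p, "sidechain")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
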