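# Rigid-body least-squares superposition (Kabsch): closed-form optimal
# rotation via SVD with reflection correction, applied ensemble-wide over
# atoms shared with a reference structure at mutually aligned positions.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Optimal least-squares rigid superposition of paired points
#'
#' Computes the rigid transform (rotation `R`, translation `t`) minimizing
#' the RMSD between `R x + t` over the moving points and the reference
#' points, by singular value decomposition of the cross-covariance matrix,
#' with the reflection branch corrected so that `det(R) = +1`.
#'
#' @param ref_points,mov_points n x 3 numeric matrices of paired
#'   coordinates (n >= 3, not all collinear).
#' @return a list with `rotation` (3 x 3 orthonormal, det +1),
#'   `translation` (3-vector) and `rmsd` (Angstrom) of the transformed
#'   moving points to the reference.
#' @export
kabsch <- function(ref_points, mov_points) {
  ref <- as.matrix(ref_points); mov <- as.matrix(mov_points)
  if (!is.numeric(ref) || !is.numeric(mov) || ncol(ref) != 3L ||
      ncol(mov) != 3L || nrow(ref) != nrow(mov))
    stop("kabsch needs two equally sized n x 3 coordinate matrices")
  n <- nrow(ref)
  if (n < 3L) stop("kabsch needs at least 3 point pairs, got ", n)
  cref <- colMeans(ref); cmov <- colMeans(mov)
  refc <- sweep(ref, 2L, cref); movc <- sweep(mov, 2L, cmov)
  if (svd(refc)$d[2L] < 1e-8 || svd(movc)$d[2L] < 1e-8)
    stop("degenerate point configuration: all points (nearly) collinear")
  sv <- svd(t(movc) %*% refc)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.vector(cref - R %*% cmov)
  moved <- movc %*% t(R)  # both sets centered; rotation only
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((moved - refc)^2))))
}

apply_transform <- function(s, rotation, translation) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  moved <- xyz %*% t(rotation) +
    matrix(translation, nrow(xyz), 3L, byrow = TRUE)
  s$atoms$x <- moved[, 1L]; s$atoms$y <- moved[, 2L]; s$atoms$z <- moved[, 3L]
  s
}

# paired coordinates of atoms shared between two structures at columns
# where both are aligned (non-gap), restricted to atom_names
matched_coordinates <- function(ref_s, mov_s, ref_cells, mov_cells,
                                atom_names) {
  ref_pts <- NULL; mov_pts <- NULL
  both <- which(!is.na(ref_cells) & !is.na(mov_cells))
  for (col in both) {
    for (nm in atom_names) {
      pr <- atom_xyz(ref_s, ref_cells[col], nm)
      pm <- atom_xyz(mov_s, mov_cells[col], nm)
      if (!is.null(pr) && !is.null(pm)) {
        ref_pts <- rbind(ref_pts, pr)
        mov_pts <- rbind(mov_pts, pm)
      }
    }
  }
  list(ref = ref_pts, mov = mov_pts)
}

#' Superpose an ensemble onto a reference structure
#'
#' Every structure is rigidly fitted onto the reference by [kabsch()] over
#' the atoms of `atom_set` that exist in both structures at alignment
#' columns where both are non-gap.  The transform is then applied to all
#' atoms of the structure.  The first structure is the reference when none
#' is named.
#'
#' @param structures list of `pdb_structure` objects.
#' @param alignment the `ensemble_alignment` binding them.
#' @param reference label of the reference structure; default the first.
#' @param atom_set `"backbone"` (N, CA, C, O; default) or `"calpha"`.
#' @return a `superposition`: list with `structures` (transformed),
#'   `transforms` (per structure: rotation, translation), `rmsd` (named,
#'   Angstrom, to the reference over the matched atoms), `atoms_used`
#'   (named counts), `reference`, `atom_set`.
#' @export
superpose_ensemble <- function(structures, alignment, reference = NULL,
                               atom_set = c("backbone", "calpha")) {
  structures <- as_structure_list(structures)
  stopifnot(inherits(alignment, "ensemble_alignment"))
  atom_set <- match.arg(atom_set)
  atom_names <- if (atom_set == "backbone") BACKBONE_ATOMS else "CA"
  labels <- vapply(structures, function(s) s$label, character(1L))
  if (is.null(reference)) reference <- labels[1L]
  iref <- match(reference, labels)
  if (is.na(iref)) stop("reference structure '", reference,
                        "' not in the ensemble")
  ref_s <- structures[[iref]]
  ref_cells <- alignment$cells[match(reference, alignment$labels), ]
  transforms <- vector("list", length(structures))
  rmsd <- numeric(length(structures)); used <- integer(length(structures))
  out <- structures
  for (i in seq_along(structures)) {
    mov_cells <- alignment$cells[match(labels[i], alignment$labels), ]
    pts <- matched_coordinates(ref_s, structures[[i]], ref_cells, mov_cells,
                               atom_names)
    n_pts <- if (is.null(pts$ref)) 0L else nrow(pts$ref)
    if (n_pts < 3L)
      stop("structure '", labels[i], "' shares only ", n_pts, " ", atom_set,
           " atom(s) with the reference; at least 3 are required")
    fit <- kabsch(pts$ref, pts$mov)
    transforms[[i]] <- fit[c("rotation", "translation")]
    rmsd[i] <- fit$rmsd
    used[i] <- n_pts
    out[[i]] <- apply_transform(structures[[i]], fit$rotation,
                                fit$translation)
  }
  names(transforms) <- names(rmsd) <- names(used) <- labels
  structure(list(structures = out, transforms = transforms, rmsd = rmsd,
                 atoms_used = used, reference = reference,
                 atom_set = atom_set),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> ", length(x$structures), " structures on '",
      x$reference, "' (", x$atom_set, " atoms)\n", sep = "")
  cat("  rmsd to reference (A): ",
      paste(sprintf("%s=%.3f", names(x$rmsd), x$rmsd), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
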