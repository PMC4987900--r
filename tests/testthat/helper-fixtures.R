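# Fixtures are built in code: hand-written PDB record text for the parser
# policies, synthetic chains/ensembles for everything downstream.

# one fixed-column ATOM record (PDB 3.3 columns)
atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                      altloc = " ", icode = " ", occ = 1, b = 0,
                      element = substr(name, 1L, 1L), record = "ATOM") {
  name4 <- if (nchar(name) >= 4L) name else sprintf(" %-3s", name)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, altloc, resid, chain, resno, icode,
          x, y, z, occ, b, element)
}

# backbone-only residue (N, CA, C, O) as four ATOM lines
residue_lines <- function(serial0, resid, chain, resno, origin,
                          icode = " ", b = 0) {
  names <- c("N", "CA", "C", "O")
  offs <- list(c(0, 0, 0), c(1.45, 0, 0), c(2.0, 1.3, 0), c(2.0, 2.5, 0))
  vapply(seq_along(names), function(k)
    atom_line(serial0 + k - 1L, names[k], resid, chain, resno,
              origin[1] + offs[[k]][1], origin[2] + offs[[k]][2],
              origin[3] + offs[[k]][3], icode = icode, b = b,
              element = substr(names[k], 1L, 1L)),
    character(1L))
}

write_pdb_text <- function(lines) {
  path <- tempfile(fileext = ".pdb")  # session tempdir, removed on exit
  writeLines(lines, path)
  path
}

# minimal structure with a single N atom at a chosen x position
single_atom_structure <- function(label, x, b = 0) {
  path <- write_pdb_text(atom_line(1L, "N", "GLY", "A", 1L, x, 0, 0, b = b))
  read_pdb(path, label = label)
}

# uniform random rotation (QR of a Gaussian matrix, det corrected to +1)
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3L))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

rigidly_move <- function(s, R = random_rotation(),
                         t = stats::rnorm(3, sd = 5)) {
  strucstats:::apply_transform(s, R, t)
}

# override the residue numbers of a built chain (atoms + residue table)
set_resnos <- function(s, resnos) {
  stopifnot(length(resnos) == nrow(s$residues))
  s$atoms$resno <- resnos[s$atoms$ridx]
  s$residues$resno <- resnos
  s
}

# two-family ensemble: torsion centers 120 degrees apart in phi and psi
# over the loop positions, wrapped-normal noise sd 5 degrees, 10 + 10
# structures -- the desk-scale two-state ensemble used across the suite
LOOP_POSITIONS <- 4:9

two_family_ensemble <- function(seed = 42L, n = 10L, sd = 5) {
  nres <- 12L
  dphi <- dpsi <- rep(0, nres)
  dphi[LOOP_POSITIONS] <- 120
  dpsi[LOOP_POSITIONS] <- 120
  build_ensemble("AKLVGFSTYEMN", n = n,
                 phi = -57, psi = -47, omega = 180,
                 families = list(
                   list(label = "stateA", dphi = 0, dpsi = 0),
                   list(label = "stateB", dphi = dphi, dpsi = dpsi)),
                 perturbation_sd = sd, seed = seed)
}

# brute-force least-squares superposition oracle: coarse grid over Euler
# angles followed by local refinement; independent of the SVD route
brute_force_rmsd <- function(ref, mov, step = 15) {
  refc <- sweep(ref, 2L, colMeans(ref))
  movc <- sweep(mov, 2L, colMeans(mov))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3L)
    Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3L)
    Rz2 <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3L)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((movc %*% t(rot(ang)) - refc)^2)))
  grid <- seq(0, 2 * pi - 1e-9, by = step * pi / 180)
  best <- c(0, 0, 0); best_v <- obj(best)
  for (a1 in grid) for (a2 in grid[grid <= pi]) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best_v) { best_v <- v; best <- c(a1, a2, a3) }
  }
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

# naive complete-linkage merge heights from stats::hclust, used as the
# independent clustering oracle
hclust_heights <- function(D) {
  sort(stats::hclust(stats::as.dist(D), method = "complete")$height)
}
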