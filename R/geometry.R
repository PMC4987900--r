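# Elementary 3D vector geometry shared by the torsion, superposition and
# builder code.  All angles at the package surface are degrees.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector where a direction is required")
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- x - 360 * floor(x / 360)   # [0, 360)
  ifelse(y > 180, y - 360, y)
}

#' Torsion (dihedral) angle of four points
#'
#' Signed angle between the plane through `p1, p2, p3` and the plane through
#' `p2, p3, p4`, using the IUPAC sign convention: looking down the central
#' `p2 -> p3` bond, a clockwise rotation of the far bond relative to the near
#' bond is positive.  A planar trans (anti) arrangement gives 180 degrees, a
#' planar cis arrangement 0.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Cartesian coordinates, Angstrom).
#' @return the torsion angle in degrees, in (-180, 180].
#' @examples
#' torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)) # 180
#' torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))  # 0
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("degenerate torsion: coincident consecutive points")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("degenerate torsion: collinear bonded triple")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * unit3(b2))
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# NeRF-style sequential placement: position a fourth atom D bonded to C given
# the three previously placed atoms A, B, C, the C-D bond length (Angstrom),
# the B-C-D bond angle and the A-B-C-D torsion (degrees).
place_atom <- function(a, b, c, length, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-length * cos(th),
          length * sin(th) * cos(ph),
          length * sin(th) * sin(ph))
  c + cbind(bc, m, n) %*% d2
}
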