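# Circular statistics on angles in degrees.  Torsion angles live on the
# circle, so dispersion and averages are computed from the vector resultant
# of the unit vectors at the sample angles, never from linear moments.

#' Circular distance between two angles
#'
#' Shortest arc between `a` and `b` on the circle, in degrees.  This is the
#' metric used for dihedral-space structure distances.
#'
#' @param a,b angles in degrees (vectors recycle).
#' @return distances in `[0, 180]`.
#' @examples
#' circ_dist(170, -170) # 20
#' circ_dist(-90, 90)   # 180
#' @export
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Circular mean of a sample of angles
#'
#' Direction of the vector resultant of the unit vectors at the sample
#' angles, mapped into (-180, 180].  The mean is undefined when the
#' resultant length is (numerically) zero, e.g. for an antipodal pair.
#'
#' @param x numeric vector of angles in degrees; `NA`s are an error
#'   (exclude undefined torsions before calling).
#' @return the circular mean in degrees.
#' @export
circular_mean <- function(x) {
  if (length(x) == 0L || anyNA(x)) stop("circular_mean needs a non-empty, NA-free sample")
  r <- deg2rad(x)
  s <- mean(sin(r))
  c <- mean(cos(r))
  if (sqrt(s^2 + c^2) <= 1e-12)
    stop("circular mean undefined: zero resultant length")
  wrap_angle(rad2deg(atan2(s, c)))
}

#' Circular standard deviation of a sample of angles
#'
#' Mardia's circular standard deviation \eqn{s = \sqrt{-2 \ln \bar R}}
#' (in radians, reported in degrees), where \eqn{\bar R} is the mean
#' resultant length of the sample.  A single observation has sd 0.
#'
#' @inheritParams circular_mean
#' @return the circular standard deviation in degrees (>= 0).
#' @examples
#' circular_sd(c(10, 10, 10))      # 0
#' circular_sd(c(0, 90))           # sqrt(-2 * log(sqrt(0.5))) in degrees
#' @export
circular_sd <- function(x) {
  if (length(x) == 0L || anyNA(x)) stop("circular_sd needs a non-empty, NA-free sample")
  r <- deg2rad(x)
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  if (rbar <= 1e-12)
    stop("circular sd undefined: zero mean resultant length")
  if (rbar > 1) rbar <- 1  # numerical guard
  rad2deg(sqrt(-2 * log(rbar)))
}

#' Per-position circular summaries of torsion angles
#'
#' Aggregates a torsion table over the ensemble: for every alignment
#' position and angle type with at least one defined value, the count,
#' circular mean and circular standard deviation are reported globally and,
#' when structure families are assigned, per family.
#'
#' @param torsions torsion table as returned by [ensemble_torsions()]
#'   (long data frame with `label`, `residue`, `angle`, `value`).
#' @param alignment an `ensemble_alignment`.
#' @param selection optional [parse_position_list()] selection restricting
#'   positions and angle types; `NULL` means all positions and all seven
#'   angle types.
#' @param families optional named character vector mapping structure labels
#'   to family labels; unnamed structures fall only into the global summary.
#' @return a data frame with columns `position`, `angle`, `family`
#'   (`"GLOBAL"` for the whole ensemble), `n`, `mean_deg`, `sd_deg`.
#' @export
position_summaries <- function(torsions, alignment, selection = NULL,
                               families = NULL) {
  stopifnot(inherits(alignment, "ensemble_alignment"))
  positions <- alignment_positions(alignment)
  angles <- ANGLE_NAMES
  if (!is.null(selection)) {
    if (!is.null(selection$ranges))
      positions <- positions[positions %in% selection_positions(selection)]
    angles <- selection$angles
  }
  long <- torsions_by_position(torsions, alignment)
  long <- long[long$position %in% positions & long$angle %in% angles &
                 !is.na(long$value), , drop = FALSE]
  if (nrow(long) == 0L)
    return(data.frame(position = integer(), angle = character(),
                      family = character(), n = integer(),
                      mean_deg = numeric(), sd_deg = numeric(),
                      stringsAsFactors = FALSE))
  long$family <- "GLOBAL"
  if (!is.null(families)) {
    fam <- families[long$label]
    extra <- long[!is.na(fam), , drop = FALSE]
    extra$family <- fam[!is.na(fam)]
    long <- rbind(long, extra)
  }
  key <- interaction(long$position, long$angle, long$family, drop = TRUE)
  out <- do.call(rbind, lapply(split(long, key), function(g) {
    v <- g$value
    data.frame(position = g$position[1L], angle = g$angle[1L],
               family = g$family[1L], n = length(v),
               mean_deg = if (resultant_length(v) > 1e-12) circular_mean(v) else NA_real_,
               sd_deg = if (resultant_length(v) > 1e-12) circular_sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$position, match(out$angle, ANGLE_NAMES),
                   out$family != "GLOBAL", out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

resultant_length <- function(x) {
  r <- deg2rad(x)
  sqrt(mean(sin(r))^2 + mean(cos(r))^2)
}

# Attach alignment positions to a long torsion table: each (label, residue
# index) pair maps through the alignment cells to a position number.
torsions_by_position <- function(torsions, alignment) {
  cells <- alignment$cells
  pos <- alignment_positions(alignment)
  idx <- match(torsions$label, alignment$labels)
  if (anyNA(idx))
    stop("torsion table contains labels absent from the alignment: ",
         paste(unique(torsions$label[is.na(idx)]), collapse = ", "))
  position <- rep(NA_integer_, nrow(torsions))
  for (i in seq_along(alignment$labels)) {
    sel <- which(idx == i)
    if (!length(sel)) next
    colmap <- match(torsions$residue[sel], cells[i, ])
    position[sel] <- pos[colmap]
  }
  cbind(torsions, position = position)
}
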