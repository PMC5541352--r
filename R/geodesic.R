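# Geodesics: the one-parameter family of rotations mapping a candidate
# reflection direction h-hat onto an observed direction g-hat.  In
# Rodrigues-Frank space this set is a straight line anchored at the minimal
# rotation (axis h x g) with direction parallel to h + g; as a set of unit
# quaternions it is the great circle spanned by the minimal rotation and the
# half turn about h + g.

#' Geodesic of rotations mapping one direction onto another
#'
#' @param g Observed scattering vector (length 3, any non-zero magnitude).
#' @param h Candidate reflection vector (length 3, non-zero).
#' @return Object of class \code{geodesic}: list with unit quaternions
#'   \code{q_min} (minimal rotation) and \code{q_max} (half turn about
#'   \eqn{\hat h + \hat g}) spanning the solution circle, the RF-space
#'   anchor \code{r_min} and unit \code{direction} (parallel to
#'   \eqn{\hat h + \hat g}), and \code{degenerate} flag.  Antipodal input
#'   (\eqn{\hat g = -\hat h}) yields a degenerate geodesic (no finite RF
#'   anchor).
#' @export
geodesic_from_pair <- function(g, h) {
  stopifnot(length(g) == 3, length(h) == 3)
  gn <- sqrt(sum(g^2)); hn <- sqrt(sum(h^2))
  if (gn <= 0 || hn <= 0) stop("g and h must be non-zero vectors")
  gd <- g / gn; hd <- h / hn
  s <- hd + gd
  sn <- sqrt(sum(s^2))
  if (sn < 1e-9) {
    return(structure(list(q_min = NULL, q_max = NULL, r_min = NULL,
                          direction = NULL, degenerate = TRUE),
                     class = "geodesic"))
  }
  dirv <- s / sn
  cr <- c(hd[2] * gd[3] - hd[3] * gd[2],
          hd[3] * gd[1] - hd[1] * gd[3],
          hd[1] * gd[2] - hd[2] * gd[1])
  crn <- sqrt(sum(cr^2))
  if (crn < 1e-14) {                      # collinear: identity is a solution
    q_min <- c(1, 0, 0, 0)
    r_min <- c(0, 0, 0)
  } else {
    ang <- atan2(crn, sum(hd * gd))
    q_min <- quat_from_axis_angle(cr, ang)
    r_min <- tan(ang / 2) * cr / crn
  }
  q_max <- quat_canonical(c(0, dirv))
  structure(list(q_min = q_min, q_max = q_max, r_min = r_min,
                 direction = dirv, degenerate = FALSE),
            class = "geodesic")
}

#' Sample rotations along a geodesic
#'
#' Returns unit quaternions \code{cos(t) q_min + sin(t) q_max}; every sampled
#' rotation maps \eqn{\hat h} onto \eqn{\hat g}.
#'
#' @param geo A \code{\link{geodesic_from_pair}} result.
#' @param t Circle parameters (radians); the full set is covered by
#'   \code{[0, pi)}.
#' @return Matrix \code{length(t) x 4} of canonical unit quaternions.
#' @export
geodesic_rotations <- function(geo, t) {
  stopifnot(inherits(geo, "geodesic"))
  if (isTRUE(geo$degenerate)) stop("degenerate (antipodal) geodesic")
  q <- outer(cos(t), geo$q_min) + outer(sin(t), geo$q_max)
  q <- q / sqrt(rowSums(q^2))
  flip <- q[, 1] < 0
  q[flip, ] <- -q[flip, ]
  q
}
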