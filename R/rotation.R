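#' @useDynLib rfindex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Rotations are represented as unit quaternions q = (w, x, y, z) in canonical
# form (first non-zero component positive), since q and -q describe the same
# rotation.  Matrices are 3x3 proper rotations acting on column vectors.

#' Canonicalize a quaternion
#'
#' Normalizes to unit length and flips the sign so that the first non-zero
#' component is positive (q and -q are the same rotation).
#'
#' @param q Numeric vector of length 4, \code{(w, x, y, z)}.
#' @return Unit quaternion of length 4 in canonical form.
#' @export
quat_canonical <- function(q) {
  stopifnot(length(q) == 4, all(is.finite(q)))
  n <- sqrt(sum(q^2))
  if (n < 1e-300) stop("zero quaternion")
  q <- q / n
  nz <- which(abs(q) > 1e-14)
  if (length(nz) && q[nz[1]] < 0) q <- -q
  q
}

#' Quaternion product
#'
#' @param a,b Quaternions \code{(w, x, y, z)}.
#' @return The quaternion of the composed rotation \code{a} then applied
#'   after \code{b} (i.e. matrix product \code{R(a) \%*\% R(b)}).
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion inverse (conjugate for unit quaternions)
#' @param q Unit quaternion.
#' @return The inverse rotation's quaternion.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Build a rotation from axis and angle
#'
#' @param axis Rotation axis (any non-zero 3-vector; normalized internally).
#' @param angle Rotation angle in radians.
#' @return Canonical unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-300) stop("zero rotation axis")
  quat_canonical(c(cos(angle / 2), sin(angle / 2) * axis / n))
}

#' Axis and angle of a rotation
#'
#' @param q Unit quaternion.
#' @return List with \code{axis} (unit 3-vector) and \code{angle} in
#'   radians, \code{angle} in \code{[0, pi]}. The axis of the identity is
#'   reported as \code{c(0, 0, 1)} by convention.
#' @export
quat_to_axis_angle <- function(q) {
  q <- quat_canonical(q)
  s <- sqrt(sum(q[2:4]^2))
  ang <- 2 * atan2(s, abs(q[1]))
  if (s < 1e-14) return(list(axis = c(0, 0, 1), angle = 0))
  sgn <- if (q[1] >= 0) 1 else -1
  list(axis = sgn * q[2:4] / s, angle = ang)
}

#' Rotation angle of a quaternion (radians)
#' @param q Unit quaternion, or an n x 4 matrix of them.
#' @return Angle(s) in \code{[0, pi]}.
#' @export
quat_angle <- function(q) {
  if (is.matrix(q)) return(2 * acos(pmin(1, abs(q[, 1]))))
  2 * acos(min(1, abs(q[1])))
}

#' Convert a quaternion to a rotation matrix
#' @param q Unit quaternion.
#' @return 3x3 proper rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Convert a rotation matrix to a quaternion
#' @param R 3x3 proper rotation matrix.
#' @return Canonical unit quaternion.
#' @export
matrix_to_quat <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  quat_canonical(q)
}

#' Rodrigues-Frank vector of a rotation
#'
#' The Rodrigues-Frank (RF) image of a rotation by angle \eqn{\omega} about
#' unit axis \eqn{\hat n} is \eqn{r = \hat n \tan(\omega/2)}.  It diverges as
#' \eqn{\omega \to 180^\circ}; rotations that close to a half turn must be
#' handled through the finite chart covering (\code{\link{chart_map}})
#' instead, and this function refuses them.
#'
#' @param q Unit quaternion.
#' @param eps Guard (radians): error if the rotation angle is within
#'   \code{eps} of 180 degrees. Default \code{1e-9}.
#' @return RF vector (length 3, dimensionless).
#' @export
rotation_to_rf <- function(q, eps = 1e-9) {
  q <- quat_canonical(q)
  if (2 * acos(min(1, abs(q[1]))) > pi - eps)
    stop("rotation angle at/near 180 degrees: RF vector diverges; ",
         "use chart_map() for a finite representation")
  q[2:4] / q[1]
}

#' Rotation from a Rodrigues-Frank vector
#' @param r RF vector (length 3).
#' @return Canonical unit quaternion.
#' @export
rf_to_rotation <- function(r) {
  stopifnot(length(r) == 3, all(is.finite(r)))
  quat_canonical(c(1, r) / sqrt(1 + sum(r^2)))
}

#' Map a rotation to its orientation-space chart
#'
#' Orientation space is covered by four finite congruent charts
#' ("frustums"): chart \code{k} (0-based) collects the rotations whose unit
#' quaternion has its largest-magnitude component at position \code{k + 1},
#' with local coordinates the remaining three components divided by the
#' dominant one.  Each chart domain is exactly the cube \eqn{[-1,1]^3};
#' geodesics remain straight lines in every chart and continue across the
#' shared cube faces.  Ties in the dominant component are broken toward the
#' lowest index.
#'
#' @param q Unit quaternion.
#' @return List with \code{chart} (0, 1, 2 or 3) and \code{coords} (length-3
#'   vector in \eqn{[-1,1]^3}).
#' @export
chart_map <- function(q) {
  q <- q / sqrt(sum(q^2))
  k <- which.max(abs(q))  # which.max takes the lowest index on ties
  list(chart = k - 1L, coords = q[-k] / q[k])
}

#' Rotation from chart coordinates (inverse of \code{chart_map})
#' @param chart Chart id in 0..3.
#' @param coords Local coordinates (length 3, each in \eqn{[-1,1]}).
#' @return Canonical unit quaternion.
#' @export
chart_unmap <- function(chart, coords) {
  stopifnot(chart %in% 0:3, length(coords) == 3)
  q <- append(coords, 1, after = chart)
  quat_canonical(q)
}

#' Orientation at the center of an accumulator voxel
#'
#' @param chart Chart id in 0..3.
#' @param ijk Voxel address, 1-based integer vector \code{(i, j, k)} along
#'   the three local axes.
#' @param nv Voxels per axis.
#' @return Canonical unit quaternion of the voxel-center orientation.
#' @export
voxel_to_rotation <- function(chart, ijk, nv) {
  stopifnot(chart %in% 0:3, length(ijk) == 3, nv >= 1)
  if (any(ijk < 1 | ijk > nv)) stop("voxel index out of range 1..nv")
  h <- 2 / nv
  chart_unmap(chart, -1 + (ijk - 0.5) * h)
}

#' Draw uniformly random rotations
#'
#' Uniform on the rotation group: four independent standard normals,
#' normalized to a unit quaternion (and sign-canonicalized).  Uses R's RNG,
#' so results are reproducible under \code{set.seed}.
#'
#' @param n Number of rotations.
#' @return An \code{n x 4} matrix of canonical unit quaternions.
#' @export
random_rotation <- function(n = 1) {
  m <- matrix(stats::rnorm(4 * n), n, 4)
  m <- m / sqrt(rowSums(m^2))
  flip <- m[, 1] < 0
  m[flip, ] <- -m[flip, ]
  m
}
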