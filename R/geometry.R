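# Scattering geometry: detector peaks <-> reciprocal-space g vectors, and
# spot prediction for a given orientation.
#
# Lab frame: beam along +x; flat detector plane perpendicular to the beam at
# distance L.  Detector coordinates (x_m, y_m) are in metres relative to the
# beam centre, with detector x along lab y and detector y along lab z.  The
# azimuth eta is measured in the detector plane from the detector x axis
# toward the detector y axis, so a spot at scattering angle 2theta and
# azimuth eta sits at L * tan(2theta) * (cos eta, sin eta).

.HC_EV_NM <- 1239.8419843320026  # h*c in eV * nm

#' Photon energy (eV) to wavelength (nm)
#' @param energy_ev Photon energy in eV.
#' @return Wavelength in nm.
#' @export
energy_to_wavelength <- function(energy_ev) {
  stopifnot(energy_ev > 0)
  .HC_EV_NM / energy_ev
}

#' Construct a beam/detector geometry
#'
#' @param wavelength Wavelength in nm (alternatively give \code{energy_ev}).
#' @param energy_ev Photon energy in eV; converted via lambda = hc/E.
#' @param distance Sample-detector distance in metres.
#' @param pixel_size Detector pixel size in metres.
#' @param detector_half Half-extent of the (square) detector in metres;
#'   spots beyond it are not recordable.
#' @return An object of class \code{beam_geometry}.
#' @export
beam_geometry <- function(wavelength = NULL, energy_ev = NULL, distance,
                          pixel_size = 110e-6, detector_half = 0.085) {
  if (is.null(wavelength)) {
    if (is.null(energy_ev)) stop("give either wavelength (nm) or energy_ev")
    wavelength <- energy_to_wavelength(energy_ev)
  }
  stopifnot(wavelength > 0, distance > 0, pixel_size > 0, detector_half > 0)
  structure(list(wavelength = wavelength, distance = distance,
                 pixel_size = pixel_size, detector_half = detector_half),
            class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf(
    "beam geometry: lambda %.5g nm, L %.4g m, pixel %.3g m, half-extent %.3g m\n",
    x$wavelength, x$distance, x$pixel_size, x$detector_half))
  invisible(x)
}

#' Map detector peaks to reciprocal-space g vectors
#'
#' Each peak is assumed to lie on the Ewald sphere: \eqn{g = k_{out} -
#' k_{in}} with \eqn{|k_{in}| = |k_{out}| = 1/\lambda}, \eqn{k_{in}} along
#' +x and \eqn{k_{out}} pointing from the sample to the peak.
#'
#' @param peaks Two-column matrix or data frame of detector coordinates
#'   \code{(x_m, y_m)} in metres relative to the beam centre.
#' @param geom A \code{\link{beam_geometry}}.
#' @return Matrix \code{n x 3} of g vectors (nm^-1) with attribute columns
#'   \code{twotheta} and \code{eta} (radians) and \code{mag} (nm^-1).
#' @export
peak_to_gvector <- function(peaks, geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  xy <- as.matrix(peaks)[, 1:2, drop = FALSE]
  if (!all(is.finite(xy))) stop("peak coordinates must be finite")
  r <- sqrt(rowSums(xy^2))
  if (any(r < 1e-12))
    stop("peak at the beam centre: scattering direction undefined")
  L <- geom$distance
  norm3 <- sqrt(L^2 + r^2)
  kmag <- 1 / geom$wavelength
  kout <- cbind(L, xy[, 1], xy[, 2]) / norm3 * kmag
  g <- kout - cbind(kmag, 0, 0)[rep(1, nrow(kout)), , drop = FALSE]
  colnames(g) <- c("gx", "gy", "gz")
  attr(g, "twotheta") <- atan2(r, L)
  attr(g, "eta") <- atan2(xy[, 2], xy[, 1]) %% (2 * pi)
  attr(g, "mag") <- sqrt(rowSums(g^2))
  g
}

#' Project reciprocal vectors onto the detector
#'
#' Intersects the outgoing ray \eqn{k_{out} = g + k_{in}} with the detector
#' plane.  Backscattered rays (non-positive beam-direction component) and
#' positions beyond the detector extent are flagged not recordable rather
#' than raising an error.
#'
#' @param g Matrix \code{n x 3} of g vectors (nm^-1).
#' @param geom A \code{\link{beam_geometry}}.
#' @return Data frame with \code{x_m}, \code{y_m} and logical
#'   \code{recordable}.
#' @export
gvector_to_detector <- function(g, geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  g <- matrix(as.numeric(g), ncol = 3)
  kmag <- 1 / geom$wavelength
  kout <- cbind(g[, 1] + kmag, g[, 2], g[, 3])
  fwd <- kout[, 1] > 1e-12 * kmag
  scale <- ifelse(fwd, geom$distance / kout[, 1], NA_real_)
  x_m <- scale * kout[, 2]
  y_m <- scale * kout[, 3]
  rec <- fwd & !is.na(x_m) &
    abs(x_m) <= geom$detector_half & abs(y_m) <= geom$detector_half
  data.frame(x_m = x_m, y_m = y_m, recordable = rec)
}

#' Predict recordable Bragg spots for an oriented crystal
#'
#' Rotates every in-resolution, centering-allowed reflection by the crystal
#' orientation and keeps those whose reciprocal point lies within the
#' excitation tolerance \code{r_profile} of the Ewald sphere (spherical
#' partiality model), then projects them onto the detector.
#'
#' @param orientation Unit quaternion or 3x3 rotation matrix U; the
#'   reciprocal point of reflection hkl is \code{U \%*\% B \%*\% hkl}.
#' @param cell A \code{\link{unit_cell}} (ignored if \code{families} given).
#' @param geom A \code{\link{beam_geometry}}.
#' @param d_min Resolution cutoff (nm).
#' @param r_profile Excitation (profile) radius in nm^-1; a reflection is
#'   recorded when the distance of its reciprocal point from the Ewald
#'   sphere is at most this.
#' @param families Optional precomputed \code{\link{generate_families}}
#'   result for this cell and d_min (avoids re-enumeration).
#' @return Data frame sorted by \code{(h, k, l)}: indices, reciprocal point
#'   \code{gx, gy, gz} (nm^-1), excitation error \code{excit} (nm^-1),
#'   detector position \code{x_m, y_m}.  Only recordable spots are returned.
#' @export
predict_spots <- function(orientation, cell, geom, d_min, r_profile,
                          families = NULL) {
  stopifnot(r_profile >= 0)
  if (is.null(families)) families <- generate_families(cell, d_min)
  U <- if (is.matrix(orientation)) orientation else quat_to_matrix(orientation)
  q <- families$hvec %*% t(U)
  kmag <- 1 / geom$wavelength
  excit <- abs(sqrt((q[, 1] + kmag)^2 + q[, 2]^2 + q[, 3]^2) - kmag)
  sel <- excit <= r_profile
  if (!any(sel))
    return(data.frame(h = integer(), k = integer(), l = integer(),
                      gx = numeric(), gy = numeric(), gz = numeric(),
                      excit = numeric(), x_m = numeric(), y_m = numeric()))
  hkl <- families$hkl[sel, , drop = FALSE]
  qs <- q[sel, , drop = FALSE]
  det <- gvector_to_detector(qs, geom)
  rec <- det$recordable
  out <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    gx = qs[, 1], gy = qs[, 2], gz = qs[, 3],
                    excit = excit[sel], x_m = det$x_m, y_m = det$y_m)[rec, ]
  out <- out[order(out$h, out$k, out$l), ]
  rownames(out) <- NULL
  out
}
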