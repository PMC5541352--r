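# Indexer tuning parameters and the named simulation scenarios.

#' Indexer tuning parameters
#'
#' All angular tolerances are in degrees, reciprocal lengths in nm^-1,
#' direct lengths in nm.
#'
#' @param n_voxels Voxels per axis of each orientation-space chart.
#' @param v_min Minimum geodesic visits for a voxel to seed a candidate.
#' @param f_v Fraction in \code{[0,1]}: a candidate voxel must also reach
#'   \code{f_v} times the most-visited voxel's count.
#' @param sigma_2theta Estimated uncertainty of the scattering angle 2theta
#'   (degrees); drives the g-magnitude pairing tolerance through the Bragg
#'   derivative.
#' @param sigma Dimensionless scale factor on the magnitude tolerance.
#' @param sigma_eta Estimated azimuthal uncertainty (degrees); with
#'   \code{sigma_2theta} it builds the angular matching bound.
#' @param delta_omega_max Pre-selection bound (degrees) on the equivalent
#'   rotation about the reference axis bringing a predicted point onto an
#'   observed g vector.
#' @param n_min Minimum matched g vectors surviving outlier removal.
#' @param c_min Minimum completeness (matched / predicted recordable spots).
#' @param u_max Uniqueness threshold: a candidate sharing more than this
#'   fraction of its matched peaks with an accepted solution is dropped.
#' @param d_min Resolution cutoff (nm).
#' @param r_profile Excitation (profile) radius (nm^-1) used for spot
#'   prediction and completeness.
#' @param omega_axis Reference axis for the pre-selection rotation:
#'   \code{"z"} (lab vertical, default) or \code{"x"} (beam axis).
#' @param max_candidates Refinement cap: at most this many
#'   symmetry-distinct candidate voxels are refined per image.
#' @return Object of class \code{felix_params}.
#' @export
felix_params <- function(n_voxels, v_min = 30, f_v = 0.5, sigma_2theta = 0.15,
                         sigma = 0.2, sigma_eta = 0.15, delta_omega_max = 30,
                         n_min = 20, c_min = 0.5, u_max = 0.5, d_min,
                         r_profile = 0.0086, omega_axis = "z",
                         max_candidates = 200) {
  stopifnot(n_voxels >= 2, v_min >= 1, f_v >= 0, f_v <= 1,
            sigma_2theta > 0, sigma > 0, sigma_eta > 0, delta_omega_max > 0,
            n_min >= 1, c_min >= 0, c_min <= 1, u_max >= 0, u_max <= 1,
            d_min > 0, r_profile >= 0, max_candidates >= 1)
  omega_axis <- match.arg(omega_axis, c("z", "x"))
  structure(list(n_voxels = as.integer(n_voxels), v_min = v_min, f_v = f_v,
                 sigma_2theta = sigma_2theta, sigma = sigma,
                 sigma_eta = sigma_eta, delta_omega_max = delta_omega_max,
                 n_min = as.integer(n_min), c_min = c_min, u_max = u_max,
                 d_min = d_min, r_profile = r_profile,
                 omega_axis = omega_axis,
                 max_candidates = as.integer(max_candidates)),
            class = "felix_params")
}

#' @export
print.felix_params <- function(x, ...) {
  cat(sprintf("indexer parameters: N_v=%d, V_min=%g, f_V=%g\n",
              x$n_voxels, x$v_min, x$f_v))
  cat(sprintf("  sigma_2theta=%g deg, sigma_eta=%g deg, sigma=%g, dOmega<=%g deg\n",
              x$sigma_2theta, x$sigma_eta, x$sigma, x$delta_omega_max))
  cat(sprintf("  N_min=%d, c_min=%g, u_max=%g, d_min=%g nm, r_profile=%g 1/nm\n",
              x$n_min, x$c_min, x$u_max, x$d_min, x$r_profile))
  invisible(x)
}

#' Named simulation scenarios
#'
#' Three standard multi-crystal snapshot scenarios spanning the cubic,
#' tetragonal and monoclinic crystal systems: the zeolite RHO-G6 (I-centred
#' cubic, a = 6.39 nm, 9000 eV, 0.090 m, 2.0 A cutoff), hen egg-white
#' lysozyme (tetragonal 7.90 x 7.90 x 3.80 nm, 9340 eV, 0.090 m, 3.0 A) and
#' the GPCR AT1R (C-centred monoclinic 7.28 x 4.10 x 16.77 nm, beta = 99.4
#' deg, 7800 eV, 0.130 m, 3.0 A), each with its tuned indexer parameters
#' (N_v 300/400/600, f_V 0.7/0.5/0.3, sigma_2theta = sigma_eta
#' 0.3/0.15/0.15 deg).
#'
#' @param name \code{"rho-g6"}, \code{"lysozyme"} or \code{"at1r"}.
#' @param noise Optional noise model overriding the noise-free default:
#'   list with \code{pos_sigma_mm} (Gaussian positional jitter, mm),
#'   \code{miss_rate} and \code{spurious_rate} (expected spurious peaks per
#'   image).
#' @return Object of class \code{scenario}: list with \code{name},
#'   \code{cell}, \code{geom}, \code{params} (a \code{\link{felix_params}})
#'   and \code{noise}.
#' @export
scenario <- function(name = c("rho-g6", "lysozyme", "at1r"), noise = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    "rho-g6" = list(
      cell = unit_cell(6.39, 6.39, 6.39, laue_class = "m-3m", centering = "I"),
      energy = 9000, distance = 0.090, d_min = 0.20,
      n_voxels = 300, f_v = 0.7, sig = 0.30),
    "lysozyme" = list(
      cell = unit_cell(7.90, 7.90, 3.80, laue_class = "4/mmm", centering = "P"),
      energy = 9340, distance = 0.090, d_min = 0.30,
      n_voxels = 400, f_v = 0.5, sig = 0.15),
    "at1r" = list(
      cell = unit_cell(7.28, 4.10, 16.77, beta = 99.4, laue_class = "2/m",
                       centering = "C"),
      energy = 7800, distance = 0.130, d_min = 0.30,
      n_voxels = 600, f_v = 0.3, sig = 0.15))
  nm <- list(pos_sigma_mm = 0, miss_rate = 0, spurious_rate = 0)
  if (!is.null(noise)) {
    bad <- setdiff(names(noise), names(nm))
    if (length(bad)) stop("unknown noise fields: ", paste(bad, collapse = ", "))
    nm[names(noise)] <- noise
  }
  structure(list(
    name = name,
    cell = def$cell,
    geom = beam_geometry(energy_ev = def$energy, distance = def$distance),
    params = felix_params(n_voxels = def$n_voxels, f_v = def$f_v,
                          sigma_2theta = def$sig, sigma_eta = def$sig,
                          d_min = def$d_min),
    noise = nm), class = "scenario")
}

#' Assemble a custom simulation scenario
#'
#' @param cell A \code{\link{unit_cell}}.
#' @param geom A \code{\link{beam_geometry}}.
#' @param params A \code{\link{felix_params}}.
#' @param noise Noise model; see \code{\link{scenario}}.
#' @param name Label used in printouts and provenance.
#' @return Object of class \code{scenario}.
#' @export
custom_scenario <- function(cell, geom, params,
                            noise = list(pos_sigma_mm = 0, miss_rate = 0,
                                         spurious_rate = 0),
                            name = "custom") {
  stopifnot(inherits(cell, "unit_cell"), inherits(geom, "beam_geometry"),
            inherits(params, "felix_params"))
  nm <- list(pos_sigma_mm = 0, miss_rate = 0, spurious_rate = 0)
  nm[names(noise)] <- noise
  structure(list(name = name, cell = cell, geom = geom, params = params,
                 noise = nm), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s'\n", x$name))
  print(x$cell)
  print(x$geom)
  print(x$params)
  cat(sprintf("  noise: pos %.3g mm, miss %.3g, spurious %.3g\n",
              x$noise$pos_sigma_mm, x$noise$miss_rate, x$noise$spurious_rate))
  invisible(x)
}
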