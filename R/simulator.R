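# Synthetic multi-crystal snapshot generator with ground truth, and the
# Poisson crystal-arrival statistics of serial data collection.

#' Draw a uniformly random crystal orientation
#'
#' Thin alias of \code{\link{random_rotation}} (uniform unit quaternions).
#'
#' @param n Number of orientations.
#' @return \code{n x 4} matrix of canonical unit quaternions.
#' @export
random_orientation <- function(n = 1) random_rotation(n)

#' Simulate one multi-crystal snapshot image
#'
#' Places the recordable Bragg spots of \code{n_crystals} uniformly random
#' orientations of the scenario's crystal on the detector (spherical
#' partiality: a reflection is recorded when its reciprocal point is within
#' \code{r_profile} of the Ewald sphere), records per-spot ground-truth
#' provenance, then applies the scenario noise model: Gaussian positional
#' jitter, random peak loss, and spurious uniform peaks.  Spots from
#' different crystals that land within one pixel of each other are merged
#' into a single peak carrying both provenances.
#'
#' @param n_crystals Number of crystals in the image (>= 0).
#' @param scn A \code{\link{scenario}}.
#' @param families Optional precomputed reflection families for the
#'   scenario cell and d_min.
#' @param orientations Optional \code{n_crystals x 4} quaternion matrix of
#'   fixed crystal orientations (e.g. planted agglomerates); random when
#'   omitted.
#' @return Object of class \code{synthetic_image}: list with
#'   \describe{
#'     \item{peaks}{data frame \code{x_m, y_m} of observed peaks.}
#'     \item{orientations}{\code{n_crystals x 4} true quaternions.}
#'     \item{provenance}{data frame \code{peak_index, crystal, h, k, l}
#'       recorded before noise (one row per contributing reflection;
#'       \code{crystal = NA} marks spurious peaks).}
#'   }
#' @export
simulate_image <- function(n_crystals, scn, families = NULL,
                           orientations = NULL) {
  stopifnot(inherits(scn, "scenario"), n_crystals >= 0)
  if (is.null(families))
    families <- generate_families(scn$cell, scn$params$d_min)
  quats <- if (!is.null(orientations)) {
    stopifnot(nrow(orientations) == n_crystals)
    orientations
  } else if (n_crystals > 0) {
    random_orientation(n_crystals)
  } else matrix(numeric(), 0, 4)
  xs <- numeric(); ys <- numeric()
  prov <- data.frame(peak_index = integer(), crystal = integer(),
                     h = integer(), k = integer(), l = integer())
  for (ci in seq_len(n_crystals)) {
    sp <- predict_spots(quats[ci, ], scn$cell, scn$geom, scn$params$d_min,
                        scn$params$r_profile, families = families)
    if (nrow(sp) == 0) next
    idx <- length(xs) + seq_len(nrow(sp))
    xs <- c(xs, sp$x_m); ys <- c(ys, sp$y_m)
    prov <- rbind(prov, data.frame(peak_index = idx, crystal = ci,
                                   h = sp$h, k = sp$k, l = sp$l))
  }
  # merge spots from different crystals closer than one pixel (bucketed by
  # pixel-sized cells; provenance of all contributors is kept)
  if (length(xs) > 1) {
    key <- paste(round(xs / scn$geom$pixel_size),
                 round(ys / scn$geom$pixel_size))
    gid <- match(key, unique(key))
    if (max(gid) < length(xs)) {
      xs2 <- as.numeric(tapply(xs, gid, mean))
      ys2 <- as.numeric(tapply(ys, gid, mean))
      prov$peak_index <- gid[prov$peak_index]
      xs <- xs2; ys <- ys2
    }
  }
  # noise model (applied after provenance is recorded)
  nz <- scn$noise
  if (length(xs) > 0 && nz$pos_sigma_mm > 0) {
    xs <- xs + stats::rnorm(length(xs), 0, nz$pos_sigma_mm * 1e-3)
    ys <- ys + stats::rnorm(length(ys), 0, nz$pos_sigma_mm * 1e-3)
  }
  if (length(xs) > 0 && nz$miss_rate > 0) {
    keep <- stats::runif(length(xs)) >= nz$miss_rate
    remap <- cumsum(keep)
    prov <- prov[keep[prov$peak_index], , drop = FALSE]
    prov$peak_index <- remap[prov$peak_index]
    xs <- xs[keep]; ys <- ys[keep]
  }
  if (nz$spurious_rate > 0) {
    n_sp <- stats::rpois(1, nz$spurious_rate)
    if (n_sp > 0) {
      half <- scn$geom$detector_half
      sx <- stats::runif(n_sp, -half, half)
      sy <- stats::runif(n_sp, -half, half)
      idx <- length(xs) + seq_len(n_sp)
      xs <- c(xs, sx); ys <- c(ys, sy)
      prov <- rbind(prov, data.frame(peak_index = idx, crystal = NA_integer_,
                                     h = NA_integer_, k = NA_integer_,
                                     l = NA_integer_))
    }
  }
  structure(list(peaks = data.frame(x_m = xs, y_m = ys),
                 orientations = quats, provenance = prov,
                 scenario = scn$name),
            class = "synthetic_image")
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf("synthetic image (%s): %d peaks from %d crystal(s)\n",
              x$scenario, nrow(x$peaks), nrow(x$orientations)))
  invisible(x)
}

#' Simulate an ensemble of images with Poisson crystal counts
#'
#' @param lambda Mean crystals per image (>= 0).
#' @param n_images Number of images.
#' @param scn A \code{\link{scenario}}.
#' @param families Optional precomputed reflection families.
#' @return List of \code{\link{simulate_image}} results; the drawn crystal
#'   counts are attached as attribute \code{"n_crystals"}.
#' @export
poisson_image_ensemble <- function(lambda, n_images, scn, families = NULL) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (is.null(families))
    families <- generate_families(scn$cell, scn$params$d_min)
  counts <- stats::rpois(n_images, lambda)
  imgs <- lapply(counts, simulate_image, scn = scn, families = families)
  attr(imgs, "n_crystals") <- counts
  imgs
}

#' Poisson crystal-arrival expectations
#'
#' For crystals arriving independently at mean rate \code{lambda} per
#' image: the fraction of exactly-one-crystal images is
#' \eqn{\lambda e^{-\lambda}}, the hit fraction (at least one crystal) is
#' \eqn{1 - e^{-\lambda}}, and the multi-crystal fraction is
#' \eqn{1 - e^{-\lambda} - \lambda e^{-\lambda}}.  The one-crystal fraction
#' is maximized at \code{lambda = 1}, where it is \eqn{1/e} (36.8\%) at a
#' hit fraction of 63.2\%.
#'
#' @param lambda Mean crystals per image (vectorized, >= 0).
#' @return Data frame with \code{one_crystal_fraction},
#'   \code{hit_fraction} and \code{multi_crystal_fraction}.
#' @export
poisson_expectations <- function(lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  data.frame(one_crystal_fraction = lambda * exp(-lambda),
             hit_fraction = 1 - exp(-lambda),
             multi_crystal_fraction = 1 - exp(-lambda) - lambda * exp(-lambda))
}
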