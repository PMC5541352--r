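# Scoring indexing results against ground truth, and symmetry-reduced
# misorientation statistics between crystals found in the same image.

#' Symmetry-reduced misorientation between two orientations
#'
#' The minimum rotation relating two crystal orientations after accounting
#' for the crystal's proper symmetry operations; symmetric in its
#' arguments.
#'
#' @param q1,q2 Unit quaternions (or 3x3 rotation matrices).
#' @param laue_ops List of proper symmetry rotation matrices, e.g.
#'   \code{\link{laue_operators}("m-3m")}.
#' @return List with \code{angle} (degrees), \code{axis} (unit 3-vector)
#'   and \code{rf} (Rodrigues-Frank vector) of the minimizing relative
#'   rotation.
#' @export
misorientation <- function(q1, q2, laue_ops) {
  if (is.matrix(q1) && all(dim(q1) == c(3, 3))) q1 <- matrix_to_quat(q1)
  if (is.matrix(q2) && all(dim(q2) == c(3, 3))) q2 <- matrix_to_quat(q2)
  ops_q <- do.call(rbind, lapply(laue_ops, matrix_to_quat))
  q2c <- quat_conjugate(q2)
  best <- NULL
  best_w <- -1
  for (i in seq_len(nrow(ops_q))) {
    d <- quat_multiply(quat_multiply(q1, ops_q[i, ]), q2c)
    if (abs(d[1]) > best_w) {
      best_w <- abs(d[1])
      best <- quat_canonical(d)
    }
  }
  aa <- quat_to_axis_angle(best)
  rf <- if (aa$angle < pi - 1e-9) aa$axis * tan(aa$angle / 2)
        else aa$axis * Inf
  list(angle = aa$angle * 180 / pi, axis = aa$axis, rf = rf)
}

# vectorized symmetry-reduced angles (radians) between rows of Q1 and Q2
.sym_misang_pairs <- function(Q1, Q2, ops_q) {
  best <- rep(-1, nrow(Q1))
  for (i in seq_len(nrow(ops_q))) {
    o <- ops_q[i, ]
    # a = Q1 * o (row-wise quaternion product)
    a1 <- Q1[, 1] * o[1] - Q1[, 2] * o[2] - Q1[, 3] * o[3] - Q1[, 4] * o[4]
    a2 <- Q1[, 1] * o[2] + Q1[, 2] * o[1] + Q1[, 3] * o[4] - Q1[, 4] * o[3]
    a3 <- Q1[, 1] * o[3] - Q1[, 2] * o[4] + Q1[, 3] * o[1] + Q1[, 4] * o[2]
    a4 <- Q1[, 1] * o[4] + Q1[, 2] * o[3] - Q1[, 3] * o[2] + Q1[, 4] * o[1]
    # w component of a * conj(Q2)
    w <- a1 * Q2[, 1] + a2 * Q2[, 2] + a3 * Q2[, 3] + a4 * Q2[, 4]
    best <- pmax(best, abs(w))
  }
  2 * acos(pmin(1, best))
}

#' Score found orientations against ground truth
#'
#' Greedy one-to-one matching of found to true orientations per image, in
#' increasing order of symmetry-reduced misorientation; a pairing within
#' \code{tolerance_deg} counts as correctly indexed.
#'
#' @param solutions Per-image list: each element a matrix of found
#'   quaternions (rows), an \code{indexing_solutions} object, or NULL.
#' @param truth Per-image list of true orientation quaternion matrices (or
#'   \code{synthetic_image} objects).
#' @param tolerance_deg Correctness tolerance in degrees (default 1).
#' @param laue_ops Proper symmetry operators of the crystal.
#' @return Object of class \code{accuracy_report}: per-image data frame
#'   (\code{n_true}, \code{n_found}, \code{n_correct}) plus ensemble
#'   summaries \code{mean_correct} (average correctly indexed crystals per
#'   image) and \code{fraction_correct} (fraction of found crystals that
#'   are correct).
#' @export
match_to_truth <- function(solutions, truth, tolerance_deg = 1,
                           laue_ops) {
  stopifnot(tolerance_deg > 0, length(solutions) == length(truth))
  ops_q <- do.call(rbind, lapply(laue_ops, matrix_to_quat))
  as_quats <- function(x) {
    if (is.null(x)) return(matrix(numeric(), 0, 4))
    if (inherits(x, "indexing_solutions"))
      return(do.call(rbind, c(list(matrix(numeric(), 0, 4)),
                              lapply(x$solutions, function(s) s$q))))
    if (inherits(x, "synthetic_image")) return(x$orientations)
    if (is.matrix(x)) return(x)
    matrix(x, ncol = 4)
  }
  per <- data.frame(image = seq_along(truth), n_true = 0L, n_found = 0L,
                    n_correct = 0L)
  for (im in seq_along(truth)) {
    Qf <- as_quats(solutions[[im]])
    Qt <- as_quats(truth[[im]])
    per$n_true[im] <- nrow(Qt)
    per$n_found[im] <- nrow(Qf)
    if (nrow(Qf) == 0 || nrow(Qt) == 0) next
    idx <- expand.grid(f = seq_len(nrow(Qf)), t = seq_len(nrow(Qt)))
    ang <- .sym_misang_pairs(Qf[idx$f, , drop = FALSE],
                             Qt[idx$t, , drop = FALSE], ops_q)
    ord <- order(ang)
    ftaken <- logical(nrow(Qf)); ttaken <- logical(nrow(Qt))
    ncorr <- 0L
    for (r in ord) {
      if (ang[r] * 180 / pi > tolerance_deg) break
      f <- idx$f[r]; t <- idx$t[r]
      if (ftaken[f] || ttaken[t]) next
      ftaken[f] <- TRUE; ttaken[t] <- TRUE
      ncorr <- ncorr + 1L
    }
    per$n_correct[im] <- ncorr
  }
  structure(list(per_image = per,
                 mean_correct = mean(per$n_correct),
                 fraction_correct = if (sum(per$n_found) > 0)
                   sum(per$n_correct) / sum(per$n_found) else NA_real_,
                 tolerance_deg = tolerance_deg),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "accuracy over %d images (tolerance %.2g deg):\n", nrow(x$per_image),
    x$tolerance_deg))
  cat(sprintf("  true %d, found %d, correct %d\n", sum(x$per_image$n_true),
              sum(x$per_image$n_found), sum(x$per_image$n_correct)))
  cat(sprintf("  mean correctly indexed crystals/image: %.3f\n",
              x$mean_correct))
  cat(sprintf("  fraction of found crystals that are correct: %.4f\n",
              x$fraction_correct))
  invisible(x)
}

#' Misorientation survey of within-image crystal pairs
#'
#' Computes the symmetry-reduced misorientation for every unordered pair of
#' orientations found in the same image: the angle histogram, the cloud of
#' Rodrigues-Frank vectors of the minimizing relative rotations, and their
#' binned 2D projections onto the xy/yz/xz planes.
#'
#' @param per_image Per-image list of quaternion matrices (or
#'   \code{indexing_solutions}).
#' @param laue_ops Proper symmetry operators.
#' @param breaks_deg Histogram bin width in degrees.
#' @param rf_bins Number of bins per axis for the projected RF densities.
#' @return Object of class \code{misorientation_survey}: \code{angles}
#'   (degrees), \code{rf} (n x 3), \code{histogram} (counts on
#'   \code{[0, 180]}), and \code{projections} (list of xy/yz/xz count
#'   matrices with the common axis range).
#' @export
misorientation_survey <- function(per_image, laue_ops, breaks_deg = 1,
                                  rf_bins = 41) {
  as_quats <- function(x) {
    if (is.null(x)) return(matrix(numeric(), 0, 4))
    if (inherits(x, "indexing_solutions"))
      return(do.call(rbind, c(list(matrix(numeric(), 0, 4)),
                              lapply(x$solutions, function(s) s$q))))
    if (is.matrix(x)) return(x)
    matrix(x, ncol = 4)
  }
  angles <- numeric()
  rf <- matrix(numeric(), 0, 3)
  for (x in per_image) {
    Q <- as_quats(x)
    n <- nrow(Q)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      m <- misorientation(Q[i, ], Q[j, ], laue_ops)
      angles <- c(angles, m$angle)
      rf <- rbind(rf, m$rf)
    }
  }
  brk <- seq(0, 180, by = breaks_deg)
  hst <- if (length(angles))
    graphics::hist(angles, breaks = brk, plot = FALSE)$counts
  else integer(length(brk) - 1)
  lim <- if (nrow(rf)) max(abs(rf[is.finite(rowSums(rf)), ]), 0.01) else 1
  edges <- seq(-lim, lim, length.out = rf_bins + 1)
  bin2 <- function(u, v) {
    ok <- is.finite(u) & is.finite(v) & abs(u) <= lim & abs(v) <= lim
    tab <- table(factor(findInterval(u[ok], edges, all.inside = TRUE),
                        levels = seq_len(rf_bins)),
                 factor(findInterval(v[ok], edges, all.inside = TRUE),
                        levels = seq_len(rf_bins)))
    matrix(as.integer(tab), rf_bins, rf_bins)
  }
  structure(list(
    angles = angles, rf = rf,
    histogram = list(breaks = brk, counts = hst),
    projections = list(xy = bin2(rf[, 1], rf[, 2]),
                       yz = bin2(rf[, 2], rf[, 3]),
                       xz = bin2(rf[, 1], rf[, 3]),
                       edges = edges)),
    class = "misorientation_survey")
}

#' @export
print.misorientation_survey <- function(x, ...) {
  cat(sprintf("misorientation survey: %d within-image pairs\n",
              length(x$angles)))
  if (length(x$angles))
    cat(sprintf("  angles: median %.2f deg, max %.2f deg\n",
                stats::median(x$angles), max(x$angles)))
  invisible(x)
}

#' Monte-Carlo random-misorientation baseline
#'
#' Histogram density of the symmetry-reduced misorientation angle between
#' independent uniformly random rotation pairs; the reference against which
#' observed within-image misorientation distributions are compared.
#'
#' @param laue_ops Proper symmetry operators.
#' @param n_samples Number of random pairs (warning below 1000).
#' @param breaks_deg Bin width in degrees.
#' @return List with \code{breaks} (degrees), \code{density} (per degree;
#'   integrates to 1) and the raw \code{angles}.
#' @export
random_misorientation_baseline <- function(laue_ops, n_samples = 1e5,
                                           breaks_deg = 1) {
  if (n_samples < 1000)
    warning("fewer than 1000 samples: baseline will be noisy")
  ops_q <- do.call(rbind, lapply(laue_ops, matrix_to_quat))
  Q1 <- random_rotation(n_samples)
  Q2 <- random_rotation(n_samples)
  ang <- .sym_misang_pairs(Q1, Q2, ops_q) * 180 / pi
  brk <- seq(0, 180, by = breaks_deg)
  cnt <- graphics::hist(ang, breaks = brk, plot = FALSE)$counts
  list(breaks = brk, density = cnt / (n_samples * breaks_deg), angles = ang)
}
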