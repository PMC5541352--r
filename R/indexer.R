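# The indexing pipeline: candidate (g, h) pairing, geodesic accumulation,
# orientation candidates from accumulator maxima, g-vector matching,
# Procrustes refinement with outlier trimming, and solution acceptance.

# Angular matching bound (degrees) built from the two angular uncertainties.
# Isolated here so the functional form can be swapped in one place.
.eq5_bound_deg <- function(params) {
  sqrt(params$sigma_eta^2 + params$sigma_2theta^2)
}

# Relative |g| tolerance from the 2theta uncertainty via the Bragg
# derivative: |g| = 2 sin(theta)/lambda so d|g|/|g| = dtheta / tan(theta),
# with dtheta = sigma_2theta / 2.  Scaled by the dimensionless sigma.
# Isolated here for the same reason.
.magnitude_tolerance <- function(g_mag, params, wavelength) {
  sinth <- pmin(1, g_mag * wavelength / 2)
  theta <- asin(sinth)
  dtheta <- (params$sigma_2theta * pi / 180) / 2
  tol <- params$sigma * dtheta / tan(pmax(theta, 1e-6))
  pmin(tol, 0.9)  # cap: never accept a near-total magnitude mismatch
}

#' Pair observed g vectors with compatible reflections
#'
#' A reflection is a candidate for an observed g vector when their
#' reciprocal magnitudes agree within a relative tolerance derived from the
#' user's 2theta uncertainty (via the Bragg derivative) and scaled by
#' \code{sigma}.  Every symmetry-equivalent member of a compatible family is
#' listed, since each defines its own orientation geodesic.
#'
#' @param gvectors Matrix \code{n x 3} of observed g vectors (nm^-1), e.g.
#'   from \code{\link{peak_to_gvector}}.
#' @param families A \code{\link{generate_families}} result.
#' @param params A \code{\link{felix_params}}.
#' @param geom A \code{\link{beam_geometry}} (for the wavelength).
#' @return Object of class \code{candidate_pairs}: parallel integer vectors
#'   \code{g_index} and \code{member_index} (row of \code{families$hkl}),
#'   \code{family} id and relative \code{mismatch}, plus \code{n_g}.
#' @export
build_candidate_pairs <- function(gvectors, families, params, geom) {
  stopifnot(inherits(families, "reflection_families"),
            inherits(params, "felix_params"))
  G <- matrix(as.numeric(gvectors), ncol = 3)
  n_g <- nrow(G)
  gm <- sqrt(rowSums(G^2))
  tol <- .magnitude_tolerance(gm, params, geom$wavelength)
  ord <- order(families$mag)
  ms <- families$mag[ord]
  lo_val <- gm / (1 + tol)
  hi_val <- ifelse(tol < 1, gm / (1 - tol), Inf)
  lo <- findInterval(lo_val * (1 - 1e-12), ms) + 1L
  hi <- findInterval(hi_val * (1 + 1e-12), ms)
  cnt <- pmax(0L, hi - lo + 1L)
  g_index <- rep.int(seq_len(n_g), cnt)
  offs <- sequence(cnt)
  member_index <- ord[rep.int(lo, cnt) + offs - 1L]
  mism <- abs(gm[g_index] - families$mag[member_index]) /
    families$mag[member_index]
  structure(list(g_index = g_index, member_index = member_index,
                 family = families$family[member_index], mismatch = mism,
                 n_g = n_g),
            class = "candidate_pairs")
}

#' @export
print.candidate_pairs <- function(x, ...) {
  cat(sprintf("candidate pairs: %d combinations for %d g vectors\n",
              length(x$g_index), x$n_g))
  invisible(x)
}

#' Trace all candidate-pair geodesics into an accumulator
#'
#' One geodesic is traced per (g vector, equivalent reflection)
#' combination.  Degenerate (antipodal) combinations are skipped and
#' counted.
#'
#' @param pairs A \code{\link{build_candidate_pairs}} result.
#' @param gvectors The same \code{n x 3} g-vector matrix.
#' @param families The \code{\link{generate_families}} result.
#' @param acc A \code{\link{frustum_accumulator}}.
#' @return Integer vector of per-combination voxel visit counts (-1 for
#'   skipped degenerate combinations), with attribute \code{"skipped"}.
#' @export
accumulate_geodesics <- function(pairs, gvectors, families, acc) {
  stopifnot(inherits(pairs, "candidate_pairs"),
            inherits(acc, "frustum_accumulator"))
  if (length(pairs$g_index) == 0) return(structure(integer(), skipped = 0L))
  G <- matrix(as.numeric(gvectors), ncol = 3)
  visits <- acc_trace_pairs(acc$ptr, G, families$hvec,
                            pairs$g_index - 1L, pairs$member_index - 1L)
  attr(visits, "skipped") <- sum(visits < 0L)
  visits
}

#' Match observed g vectors to the lattice of a candidate orientation
#'
#' For each observed g, the magnitude-compatible equivalent reflection
#' minimizing the angular deviation to the predicted reciprocal point
#' \code{U B hkl} is assigned, provided (a) the equivalent rotation about
#' the reference axis bringing the prediction onto g is within
#' \code{delta_omega_max} (pre-selection) and (b) the angular deviation is
#' within the matching bound.  Assignment is greedy by smallest deviation
#' and one-to-one in both directions.
#'
#' @param orientation Unit quaternion or 3x3 matrix U.
#' @param gvectors Matrix \code{n x 3} of observed g vectors.
#' @param families A \code{\link{generate_families}} result.
#' @param params A \code{\link{felix_params}}.
#' @param pairs Optional precomputed \code{\link{build_candidate_pairs}}
#'   (recommended; required if \code{geom} is absent).
#' @param geom A \code{\link{beam_geometry}}, needed only to build pairs.
#' @param tol_deg Matching bound override in degrees; default
#'   \code{sqrt(sigma_eta^2 + sigma_2theta^2)}.
#' @return Data frame: \code{g_index}, \code{member_index}, \code{h, k, l},
#'   \code{deviation} (degrees).
#' @export
match_gvectors <- function(orientation, gvectors, families, params,
                           pairs = NULL, geom = NULL, tol_deg = NULL) {
  if (is.null(pairs)) {
    if (is.null(geom)) stop("give either precomputed pairs or geom")
    pairs <- build_candidate_pairs(gvectors, families, params, geom)
  }
  U <- if (is.matrix(orientation)) orientation else quat_to_matrix(orientation)
  G <- matrix(as.numeric(gvectors), ncol = 3)
  if (is.null(tol_deg)) tol_deg <- .eq5_bound_deg(params)
  if (length(pairs$g_index) == 0 || nrow(G) == 0)
    return(data.frame(g_index = integer(), member_index = integer(),
                      h = integer(), k = integer(), l = integer(),
                      deviation = numeric()))
  RH <- families$hvec %*% t(U)
  axis <- if (params$omega_axis == "z") 2L else 0L
  res <- match_combos(RH, G, pairs$g_index - 1L, pairs$member_index - 1L,
                      tol_deg * pi / 180,
                      params$delta_omega_max * pi / 180, axis)
  got <- which(res$h_index >= 0L)
  mi <- res$h_index[got] + 1L
  data.frame(g_index = got, member_index = mi,
             h = families$hkl[mi, 1], k = families$hkl[mi, 2],
             l = families$hkl[mi, 3],
             deviation = res$deviation[got] * 180 / pi)
}

#' Refine an orientation against its matched g vectors
#'
#' Iteratively solves the orthogonal-Procrustes problem aligning the unit
#' reflection vectors to the observed unit g vectors (Kabsch/SVD), then
#' drops matches with angular residual exceeding
#' \code{max(3 sigma_eta, 3 * median residual)}; repeats until stable or
#' \code{max_iter} rounds.
#'
#' @param orientation Starting orientation (quaternion or matrix).
#' @param matched A \code{\link{match_gvectors}} result.
#' @param gvectors The observed g-vector matrix.
#' @param families The \code{\link{generate_families}} result.
#' @param params A \code{\link{felix_params}}.
#' @param max_iter Maximum trim iterations.
#' @return \code{NULL} when underdetermined (fewer than 2 surviving or
#'   collinear matches); otherwise a list with \code{q} (quaternion),
#'   \code{U} (matrix) and the surviving \code{matched} data frame with
#'   updated deviations.
#' @export
refine_orientation <- function(orientation, matched, gvectors, families,
                               params, max_iter = 10) {
  G <- matrix(as.numeric(gvectors), ncol = 3)
  keep <- seq_len(nrow(matched))
  if (length(keep) < 2) return(NULL)
  gd_all <- G[matched$g_index, , drop = FALSE]
  gd_all <- gd_all / sqrt(rowSums(gd_all^2))
  hd_all <- families$hvec[matched$member_index, , drop = FALSE]
  hd_all <- hd_all / sqrt(rowSums(hd_all^2))
  U <- NULL
  ang <- NULL
  for (it in seq_len(max_iter)) {
    gd <- gd_all[keep, , drop = FALSE]
    hd <- hd_all[keep, , drop = FALSE]
    M <- t(gd) %*% hd
    sv <- svd(M)
    if (sv$d[2] < 1e-8 * sv$d[1]) return(NULL)  # collinear: underdetermined
    s3 <- sign(det(sv$u %*% t(sv$v)))
    U <- sv$u %*% diag(c(1, 1, s3)) %*% t(sv$v)
    ang <- acos(pmin(1, pmax(-1, rowSums((hd %*% t(U)) * gd))))
    thr <- max(3 * params$sigma_eta * pi / 180, 3 * stats::median(ang))
    drop <- ang > thr
    if (!any(drop)) break
    keep <- keep[!drop]
    if (length(keep) < 2) return(NULL)
  }
  gd <- gd_all[keep, , drop = FALSE]
  hd <- hd_all[keep, , drop = FALSE]
  ang <- acos(pmin(1, pmax(-1, rowSums((hd %*% t(U)) * gd))))
  out <- matched[keep, , drop = FALSE]
  out$deviation <- ang * 180 / pi
  rownames(out) <- NULL
  list(q = matrix_to_quat(U), U = U, matched = out)
}

# symmetry-reduced misorientation angles (radians) between one quaternion
# and a matrix of quaternions, given the Laue operator quaternions
.sym_misang <- function(q, Q, ops_q) {
  best <- rep(0, nrow(Q))
  for (i in seq_len(nrow(ops_q))) {
    qs <- quat_multiply(q, ops_q[i, ])
    w <- abs(Q[, 1] * qs[1] + Q[, 2] * qs[2] + Q[, 3] * qs[3] +
               Q[, 4] * qs[4])
    best <- pmax(best, w)
  }
  2 * acos(pmin(1, best))
}

.laue_quats <- function(laue_class) {
  ops <- laue_operators(laue_class)
  do.call(rbind, lapply(ops, matrix_to_quat))
}

#' Accept, deduplicate and rank candidate solutions
#'
#' Keeps candidates with at least \code{n_min} matched g vectors and
#' completeness at least \code{c_min}; then, processing in order of
#' decreasing match count, drops any candidate whose matched peak set
#' overlaps an already accepted solution by more than \code{u_max}
#' (normalized by the smaller set).
#'
#' @param drafts List of draft solutions (each with \code{n_matched},
#'   \code{completeness} and \code{matched}).
#' @param params A \code{\link{felix_params}}.
#' @return The accepted subset, sorted by \code{n_matched} descending.
#' @export
accept_solutions <- function(drafts, params) {
  ok <- vapply(drafts, function(s)
    s$n_matched >= params$n_min &&
      is.finite(s$completeness) && s$completeness >= params$c_min,
    logical(1))
  drafts <- drafts[ok]
  if (!length(drafts)) return(list())
  ord <- order(-vapply(drafts, function(s) s$n_matched, numeric(1)),
               -vapply(drafts, function(s) s$visits %||% 0, numeric(1)))
  drafts <- drafts[ord]
  accepted <- list()
  sets <- list()
  for (s in drafts) {
    gset <- s$matched$g_index
    dup <- FALSE
    for (t in sets) {
      ov <- length(intersect(gset, t)) / min(length(gset), length(t))
      if (ov > params$u_max) { dup <- TRUE; break }
    }
    if (!dup) {
      accepted <- c(accepted, list(s))
      sets <- c(sets, list(gset))
    }
  }
  accepted
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Index one snapshot image
#'
#' Full pipeline: map peaks to g vectors (if needed), pair them with
#' reflection families, trace one orientation geodesic per candidate
#' combination through the voxelized orientation space, seed candidate
#' orientations from qualified accumulator maxima (symmetry-deduplicated,
#' capped at \code{max_candidates}), match and refine each candidate, and
#' accept solutions by match count, completeness and uniqueness.
#'
#' @param peaks Data frame / matrix of detector peaks (\code{x_m, y_m}).
#'   Alternatively supply \code{gvectors} directly.
#' @param cell A \code{\link{unit_cell}}.
#' @param geom A \code{\link{beam_geometry}}.
#' @param params A \code{\link{felix_params}}.
#' @param gvectors Optional \code{n x 3} matrix of g vectors (nm^-1).
#' @param families Optional precomputed \code{\link{generate_families}}.
#' @param acc Optional \code{\link{frustum_accumulator}} (with
#'   \code{nv == params$n_voxels}) to reuse across images; it is reset.
#' @param verbose Print progress notes.
#' @return Object of class \code{indexing_solutions}: list with
#'   \code{solutions} (each: quaternion \code{q}, matrix \code{U}, oriented
#'   reciprocal basis \code{basis = U B}, \code{matched} table,
#'   \code{n_matched}, \code{completeness}, seeding voxel \code{visits}),
#'   sorted by \code{n_matched} descending, plus bookkeeping counts.
#' @export
index_image <- function(peaks = NULL, cell, geom, params, gvectors = NULL,
                        families = NULL, acc = NULL, verbose = FALSE) {
  stopifnot(inherits(params, "felix_params"))
  if (is.null(gvectors)) {
    if (is.null(peaks)) stop("give peaks or gvectors")
    if (nrow(as.matrix(peaks)) == 0) {
      gvectors <- matrix(numeric(), 0, 3)
    } else {
      gvectors <- peak_to_gvector(peaks, geom)
    }
  }
  G <- matrix(as.numeric(gvectors), ncol = 3)
  empty <- structure(list(solutions = list(), n_peaks = nrow(G),
                          n_pairs = 0L, n_maxima = 0L, n_candidates = 0L,
                          params = params),
                     class = "indexing_solutions")
  if (nrow(G) == 0) return(empty)
  if (is.null(families)) families <- generate_families(cell, params$d_min)
  pairs <- build_candidate_pairs(G, families, params, geom)
  if (length(pairs$g_index) == 0) return(empty)
  if (is.null(acc)) {
    acc <- frustum_accumulator(params$n_voxels)
  } else {
    stopifnot(acc$nv == params$n_voxels)
    reset_accumulator(acc)
  }
  if (verbose)
    message(sprintf("tracing %d geodesics for %d g vectors",
                    length(pairs$g_index), nrow(G)))
  accumulate_geodesics(pairs, G, families, acc)
  maxima <- find_local_maxima(acc, params$v_min, params$f_v)
  if (verbose) message(sprintf("%d qualified local maxima", nrow(maxima)))
  if (nrow(maxima) == 0) {
    empty$n_pairs <- length(pairs$g_index)
    return(empty)
  }

  # candidate orientations; symmetry-deduplicate (maxima come sorted by
  # visits, so the most-visited representative of each cluster is kept),
  # then cap the number refined
  ops_q <- .laue_quats(cell$laue_class)
  # ~1.25 voxel diagonals (rad): tight enough to keep closely misoriented
  # distinct lattices apart; residual duplicates are caught by the
  # uniqueness overlap filter
  merge_tol <- 1.25 * 2 * sqrt(3) / params$n_voxels
  cand_q <- NULL
  cand_v <- numeric()
  for (t in seq_len(nrow(maxima))) {
    q <- voxel_to_rotation(maxima$chart[t],
                           c(maxima$i[t], maxima$j[t], maxima$k[t]),
                           params$n_voxels)
    if (is.null(cand_q)) {
      cand_q <- matrix(q, 1, 4)
      cand_v <- maxima$visits[t]
    } else {
      if (min(.sym_misang(q, cand_q, ops_q)) > merge_tol) {
        cand_q <- rbind(cand_q, q)
        cand_v <- c(cand_v, maxima$visits[t])
      }
    }
    if (length(cand_v) >= params$max_candidates) break
  }
  if (verbose)
    message(sprintf("%d symmetry-distinct candidates to refine",
                    nrow(cand_q)))

  # seeding tolerance: the matching bound can be tighter than the voxel
  # discretization, so the first match uses whichever is larger
  eq5 <- .eq5_bound_deg(params)
  seed_tol <- max(eq5, 1.5 * (2 * sqrt(3) / params$n_voxels) * 180 / pi)
  drafts <- list()
  for (t in seq_len(nrow(cand_q))) {
    m0 <- match_gvectors(cand_q[t, ], G, families, params, pairs = pairs,
                         tol_deg = seed_tol)
    r1 <- refine_orientation(cand_q[t, ], m0, G, families, params)
    if (is.null(r1)) next
    m1 <- match_gvectors(r1$q, G, families, params, pairs = pairs,
                         tol_deg = eq5)
    r2 <- refine_orientation(r1$q, m1, G, families, params)
    if (is.null(r2)) next
    pred <- predict_spots(r2$U, cell, geom, params$d_min, params$r_profile,
                          families = families)
    drafts[[length(drafts) + 1]] <- list(
      q = r2$q, U = r2$U, matched = r2$matched,
      n_matched = nrow(r2$matched),
      completeness = if (nrow(pred) > 0) nrow(r2$matched) / nrow(pred)
                     else NaN,
      visits = cand_v[t])
  }
  sols <- accept_solutions(drafts, params)
  B <- families$B
  sols <- lapply(sols, function(s) { s$basis <- s$U %*% B; s })
  structure(list(solutions = sols, n_peaks = nrow(G),
                 n_pairs = length(pairs$g_index), n_maxima = nrow(maxima),
                 n_candidates = nrow(cand_q), params = params),
            class = "indexing_solutions")
}

#' @export
print.indexing_solutions <- function(x, ...) {
  cat(sprintf("indexing result: %d solution(s) from %d peaks (%d geodesics, %d maxima)\n",
              length(x$solutions), x$n_peaks, x$n_pairs, x$n_maxima))
  for (i in seq_along(x$solutions)) {
    s <- x$solutions[[i]]
    cat(sprintf("  [%d] n_matched=%d completeness=%.3f visits=%g\n",
                i, s$n_matched, s$completeness, s$visits))
  }
  invisible(x)
}
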