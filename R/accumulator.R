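# R-side wrapper around the compiled four-chart voxel accumulator.

#' Create a frustum accumulator
#'
#' Four congruent cubic charts jointly covering orientation space, each
#' segmented into \code{nv} voxels per axis with 16-bit visit counters
#' (saturating).  Memory is \code{4 * nv^3 * 2} bytes, e.g. about 216 MB at
#' \code{nv = 300}; the object can (and for multi-image runs should) be
#' reused across images via \code{\link{acc_reset}}.
#'
#' @param nv Voxels per axis.
#' @return Object of class \code{frustum_accumulator}.
#' @export
frustum_accumulator <- function(nv) {
  stopifnot(nv >= 1)
  structure(list(ptr = acc_create(as.integer(nv)), nv = as.integer(nv)),
            class = "frustum_accumulator")
}

#' @export
print.frustum_accumulator <- function(x, ...) {
  cat(sprintf("frustum accumulator: 4 charts x %d^3 voxels, total visits %s\n",
              x$nv, format(acc_total(x$ptr), big.mark = ",")))
  invisible(x)
}

#' Reset all counters to zero
#' @param acc A \code{\link{frustum_accumulator}}.
#' @return The accumulator, invisibly.
#' @export
reset_accumulator <- function(acc) {
  acc_reset(acc$ptr)
  invisible(acc)
}

#' Total and maximum visit counts
#' @param acc A \code{\link{frustum_accumulator}}.
#' @return \code{accumulator_total}: sum of all counters;
#'   \code{accumulator_max}: largest counter.
#' @export
accumulator_total <- function(acc) acc_total(acc$ptr)

#' @rdname accumulator_total
#' @export
accumulator_max <- function(acc) acc_max(acc$ptr)

#' Counter values (small grids / diagnostics)
#'
#' \code{accumulator_counts} dumps one chart as an \code{nv^3} array
#' (guarded to \code{nv <= 64}); \code{accumulator_count_at} reads counters
#' at given addresses for any grid size.
#'
#' @param acc A \code{\link{frustum_accumulator}}.
#' @param chart Chart id (0..3).
#' @return Integer array \code{nv x nv x nv} (i fastest).
#' @export
accumulator_counts <- function(acc, chart) {
  array(acc_counts(acc$ptr, as.integer(chart)), dim = rep(acc$nv, 3))
}

#' @rdname accumulator_counts
#' @param i,j,k 1-based voxel indices (vectors recycled to equal length).
#' @export
accumulator_count_at <- function(acc, chart, i, j, k) {
  n <- max(length(chart), length(i), length(j), length(k))
  acc_count_at(acc$ptr, as.integer(rep_len(chart, n)),
               as.integer(rep_len(i, n)), as.integer(rep_len(j, n)),
               as.integer(rep_len(k, n)))
}

#' Trace one geodesic through the accumulator
#'
#' Ray-traces the geodesic through all four charts with exact cell-boundary
#' stepping (3D DDA), incrementing each visited voxel exactly once.  A
#' degenerate (antipodal) geodesic is a no-op with a warning.
#'
#' @param geo A \code{\link{geodesic_from_pair}} result.
#' @param acc A \code{\link{frustum_accumulator}}.
#' @param collect If TRUE also return the visited voxel addresses.
#' @return Number of voxels visited; if \code{collect}, a data frame of
#'   addresses (\code{chart}, \code{i}, \code{j}, \code{k}) is attached as
#'   attribute \code{"voxels"}.
#' @export
trace_geodesic <- function(geo, acc, collect = FALSE) {
  stopifnot(inherits(geo, "geodesic"), inherits(acc, "frustum_accumulator"))
  if (isTRUE(geo$degenerate)) {
    warning("degenerate (antipodal) geodesic: nothing traced")
    return(0L)
  }
  res <- acc_trace(acc$ptr, geo$q_min, geo$q_max, collect)
  n <- res$count
  if (collect)
    attr(n, "voxels") <- data.frame(chart = res$chart, i = res$i,
                                    j = res$j, k = res$k)
  n
}

#' Find qualified local maxima of the accumulator
#'
#' A voxel qualifies when its count is at least that of all its (up to 26)
#' in-chart neighbours, at least \code{v_min}, and at least \code{f_v} times
#' the global maximum count.  Plateau voxels all qualify.
#'
#' @param acc A \code{\link{frustum_accumulator}}.
#' @param v_min Minimum number of visits (>= 1).
#' @param f_v Fraction of the global maximum in \code{[0, 1]}.
#' @return Data frame (\code{chart}, \code{i}, \code{j}, \code{k},
#'   \code{visits}) sorted by visits descending, ties by (chart, linear
#'   index) ascending.
#' @export
find_local_maxima <- function(acc, v_min, f_v) {
  stopifnot(inherits(acc, "frustum_accumulator"), v_min >= 1,
            f_v >= 0, f_v <= 1)
  acc_local_maxima(acc$ptr, v_min, f_v)
}
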