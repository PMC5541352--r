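# Unit-cell algebra, Laue point-group operators and reflection families.

#' Construct a unit cell
#'
#' Cell lengths are in nanometres, angles in degrees.  Only the proper
#' rotations of the Laue class are used for symmetry (reflection families,
#' misorientation reduction); lattice-centering reflection conditions are
#' applied as a filter when generating reflections.
#'
#' @param a,b,c Cell edge lengths (nm).
#' @param alpha,beta,gamma Cell angles (degrees).
#' @param laue_class One of \code{"m-3m"}, \code{"4/mmm"}, \code{"mmm"},
#'   \code{"4/m"}, \code{"2/m"}, \code{"-1"}.
#' @param centering Lattice centering: \code{"P"}, \code{"I"}, \code{"C"} or
#'   \code{"F"}; reflections violating the centering condition are omitted.
#' @return An object of class \code{unit_cell}.
#' @examples
#' unit_cell(6.39, 6.39, 6.39, laue_class = "m-3m", centering = "I")
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      laue_class = "-1", centering = "P") {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees")
  laue_class <- match.arg(laue_class, names(.laue_generators()))
  centering <- match.arg(centering, c("P", "I", "C", "F"))
  cell <- structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         laue_class = laue_class, centering = centering),
    class = "unit_cell")
  if (cell_volume(cell) <= 0) stop("degenerate cell: non-positive volume")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4g b=%.4g c=%.4g nm, angles %.4g/%.4g/%.4g deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  cat(sprintf("  Laue class %s, centering %s, volume %.4g nm^3\n",
              x$laue_class, x$centering, cell_volume(x)))
  invisible(x)
}

#' Direct-space basis matrix
#'
#' Standard crystallographic setting: a along the lab x axis, b in the xy
#' plane, c completing a right-handed frame.  Columns are the basis vectors
#' in nm.
#'
#' @param cell A \code{\link{unit_cell}}.
#' @return 3x3 matrix with columns a, b, c.
#' @export
direct_basis <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  cz2 <- 1 - cb^2 - ((ca - cb * cg) / sg)^2
  if (cz2 <= 0) stop("degenerate cell: angles admit no 3D lattice")
  av <- c(cell$a, 0, 0)
  bv <- cell$b * c(cg, sg, 0)
  cv <- cell$c * c(cb, (ca - cb * cg) / sg, sqrt(cz2))
  cbind(a = av, b = bv, c = cv)
}

#' Unit-cell volume (nm^3)
#' @param cell A \code{\link{unit_cell}}.
#' @return Volume in nm^3.
#' @export
cell_volume <- function(cell) det(direct_basis(cell))

#' Reciprocal basis matrix
#'
#' Crystallographic (2*pi-free) convention: the reciprocal vectors satisfy
#' \eqn{a^* \cdot a = 1}, so \code{B \%*\% c(h, k, l)} has length
#' \eqn{1/d_{hkl}}.  \code{det(B) = 1/V}.
#'
#' @param cell A \code{\link{unit_cell}}.
#' @return 3x3 matrix with columns a*, b*, c* (nm^-1).
#' @export
reciprocal_basis <- function(cell) {
  A <- direct_basis(cell)
  B <- t(solve(A))
  dimnames(B) <- list(NULL, c("astar", "bstar", "cstar"))
  B
}

.laue_generators <- function() {
  rot <- function(axis, angle) quat_to_matrix(quat_from_axis_angle(axis, angle))
  list(
    "m-3m"  = list(rot(c(0, 0, 1), pi / 2), rot(c(1, 1, 1), 2 * pi / 3)),
    "4/mmm" = list(rot(c(0, 0, 1), pi / 2), rot(c(1, 0, 0), pi)),
    "4/m"   = list(rot(c(0, 0, 1), pi / 2)),
    "mmm"   = list(rot(c(0, 0, 1), pi), rot(c(1, 0, 0), pi)),
    "2/m"   = list(rot(c(0, 1, 0), pi)),   # unique axis b
    "-1"    = list()
  )
}

#' Proper rotations of a Laue class
#'
#' Returns the proper-rotation subgroup of the Laue point group as Cartesian
#' 3x3 matrices, generated by closure from class generators.  The monoclinic
#' setting uses unique axis b.
#'
#' @param laue_class Class symbol; see \code{\link{unit_cell}}.
#' @return List of 3x3 proper rotation matrices (the first is the identity).
#' @examples
#' length(laue_operators("m-3m"))  # 24
#' @export
laue_operators <- function(laue_class) {
  gens <- .laue_generators()
  if (!laue_class %in% names(gens))
    stop("unsupported Laue class '", laue_class, "'; supported: ",
         paste(names(gens), collapse = ", "))
  ops <- list(diag(3))
  keys <- paste(round(diag(3), 9), collapse = ",")
  repeat {
    grew <- FALSE
    for (g in gens[[laue_class]]) for (o in ops) {
      m <- g %*% o
      key <- paste(round(m, 9), collapse = ",")
      if (!key %in% keys) {
        ops <- c(ops, list(m))
        keys <- c(keys, key)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  ops
}

# Integer matrices acting on (h,k,l) index triples: M = B^{-1} S B.
.laue_hkl_operators <- function(cell) {
  B <- reciprocal_basis(cell)
  Binv <- solve(B)
  lapply(laue_operators(cell$laue_class), function(S) {
    M <- Binv %*% S %*% B
    Mr <- round(M)
    if (max(abs(M - Mr)) > 1e-6)
      stop("Laue class '", cell$laue_class,
           "' is incompatible with the given cell metric")
    storage.mode(Mr) <- "integer"
    Mr
  })
}

.centering_allowed <- function(hkl, centering) {
  switch(centering,
         P = rep(TRUE, nrow(hkl)),
         I = (hkl[, 1] + hkl[, 2] + hkl[, 3]) %% 2L == 0L,
         C = (hkl[, 1] + hkl[, 2]) %% 2L == 0L,
         F = (hkl[, 1] %% 2L == hkl[, 2] %% 2L) &
             (hkl[, 2] %% 2L == hkl[, 3] %% 2L))
}

#' Generate symmetry-grouped reflection families to a resolution cutoff
#'
#' Enumerates every integer reflection with \eqn{|B h| \le 1/d_{min}}
#' (excluding 000 and centering-forbidden reflections) and groups it into
#' Laue-orbit families including Friedel mates.  The family representative
#' is the lexicographically greatest triple of its orbit; families are
#' sorted by reciprocal-vector magnitude ascending.
#'
#' @param cell A \code{\link{unit_cell}}.
#' @param d_min Resolution cutoff (nm), > 0.
#' @param max_families Safety cap on the number of families.
#' @return An object of class \code{reflection_families}: a list with
#'   \describe{
#'     \item{families}{data frame: representative \code{h,k,l},
#'       magnitude \code{mag} (nm^-1), \code{d} spacing (nm),
#'       \code{multiplicity}.}
#'     \item{hkl}{integer matrix of all member reflections (one row each).}
#'     \item{hvec}{matrix of member reciprocal vectors \code{B \%*\% hkl}.}
#'     \item{mag}{member magnitudes (nm^-1).}
#'     \item{family}{family id (row of \code{families}) per member.}
#'   }
#' @export
generate_families <- function(cell, d_min, max_families = 50000) {
  stopifnot(inherits(cell, "unit_cell"), d_min > 0)
  B <- reciprocal_basis(cell)
  lim <- 1 / d_min
  nmax <- pmax(0L, as.integer(ceiling(c(cell$a, cell$b, cell$c) / d_min)))
  grid <- as.matrix(expand.grid(h = -nmax[1]:nmax[1],
                                k = -nmax[2]:nmax[2],
                                l = -nmax[3]:nmax[3]))
  storage.mode(grid) <- "integer"
  hv <- grid %*% t(B)
  mag <- sqrt(rowSums(hv^2))
  keep <- mag <= lim * (1 + 1e-12) & mag > 0
  keep <- keep & .centering_allowed(grid, cell$centering)
  grid <- grid[keep, , drop = FALSE]
  hv <- hv[keep, , drop = FALSE]
  mag <- mag[keep]
  if (nrow(grid) == 0)
    return(structure(list(
      families = data.frame(h = integer(), k = integer(), l = integer(),
                            mag = numeric(), d = numeric(),
                            multiplicity = integer()),
      hkl = grid, hvec = hv, mag = mag, family = integer(), B = B,
      cell = cell, d_min = d_min), class = "reflection_families"))

  # orbit representative: lexicographically greatest image over the Laue
  # proper rotations and Friedel inversion
  ops <- .laue_hkl_operators(cell)
  ops <- c(ops, lapply(ops, function(m) -m))
  best <- grid
  for (M in ops[-1]) {
    img <- grid %*% t(M)
    better <- img[, 1] > best[, 1] |
      (img[, 1] == best[, 1] & img[, 2] > best[, 2]) |
      (img[, 1] == best[, 1] & img[, 2] == best[, 2] & img[, 3] > best[, 3])
    best[better, ] <- img[better, , drop = FALSE]
  }
  key <- paste(best[, 1], best[, 2], best[, 3])
  # deterministic family order: by magnitude, then representative triple
  urep <- !duplicated(key)
  fam_key <- key[urep]
  fam_rep <- best[urep, , drop = FALSE]
  fam_mag <- mag[urep]
  ord <- order(fam_mag, -fam_rep[, 1], -fam_rep[, 2], -fam_rep[, 3])
  fam_key <- fam_key[ord]
  fam_rep <- fam_rep[ord, , drop = FALSE]
  fam_mag <- fam_mag[ord]
  if (length(fam_key) > max_families)
    stop("d_min = ", d_min, " nm yields ", length(fam_key),
         " families (cap ", max_families, "); increase d_min or the cap")
  fid <- match(key, fam_key)
  mult <- tabulate(fid, nbins = length(fam_key))
  # order members by family, then lexicographically
  mord <- order(fid, -grid[, 1], -grid[, 2], -grid[, 3])
  structure(list(
    families = data.frame(h = fam_rep[, 1], k = fam_rep[, 2], l = fam_rep[, 3],
                          mag = fam_mag, d = 1 / fam_mag,
                          multiplicity = mult),
    hkl = grid[mord, , drop = FALSE],
    hvec = hv[mord, , drop = FALSE],
    mag = mag[mord],
    family = fid[mord],
    B = B, cell = cell, d_min = d_min),
    class = "reflection_families")
}

#' @export
print.reflection_families <- function(x, ...) {
  cat(sprintf("reflection families: %d families, %d reflections, d_min %.3g nm\n",
              nrow(x$families), nrow(x$hkl), x$d_min))
  invisible(x)
}

#' Export a family list as TSV
#'
#' Columns: h k l mag d multiplicity (representative triples).
#'
#' @param families A \code{reflection_families} object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_families <- function(families, path) {
  stopifnot(inherits(families, "reflection_families"))
  utils::write.table(families$families, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
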