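# Unit-cell algebra, Laue operators, reflection families.

test_that("Laue operator sets are proper rotation groups of the right order", {
  expected <- c("m-3m" = 24L, "4/mmm" = 8L, "4/m" = 4L, "mmm" = 4L,
                "2/m" = 2L, "-1" = 1L)
  for (cls in names(expected)) {
    ops <- laue_operators(cls)
    expect_length(ops, expected[[cls]])
    keys <- vapply(ops, function(m) paste(round(m, 9), collapse = ","), "")
    expect_false(any(duplicated(keys)))
    for (m in ops) {
      expect_equal(t(m) %*% m, diag(3), tolerance = 1e-12)
      expect_equal(det(m), 1, tolerance = 1e-12)
      # inverse present
      expect_true(paste(round(t(m), 9), collapse = ",") %in% keys)
    }
    # closure under multiplication
    for (m1 in ops) for (m2 in ops)
      expect_true(paste(round(m1 %*% m2, 9), collapse = ",") %in% keys)
    expect_true(paste(round(diag(3), 9), collapse = ",") %in% keys)
  }
  expect_error(laue_operators("6/mmm"), "supported")
})

test_that("cell validation rejects degenerate inputs", {
  expect_error(unit_cell(-1, 1, 1), "positive")
  expect_error(unit_cell(1, 1, 1, alpha = 0), "between")
  # gamma exceeds alpha + beta: no 3D lattice realizes these angles
  expect_error(unit_cell(1, 1, 1, alpha = 10, beta = 80, gamma = 100))
})

test_that("standard-scenario cell volumes round-trip within 0.5%", {
  vols <- c("rho-g6" = 261.4, "lysozyme" = 237.1, "at1r" = 493.8)
  for (nm in names(vols)) {
    scn <- scenario(nm)
    expect_lt(abs(cell_volume(scn$cell) - vols[[nm]]) / vols[[nm]], 0.005)
    B <- reciprocal_basis(scn$cell)
    expect_equal(det(B) * cell_volume(scn$cell), 1, tolerance = 1e-9)
  }
})

test_that("reciprocal basis has the defining metric properties", {
  # cubic: diagonal 1/a
  cub <- unit_cell(6.39, 6.39, 6.39, laue_class = "m-3m")
  expect_equal(reciprocal_basis(cub), diag(1 / 6.39, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # tetragonal: |c*| = 1/c
  tet <- unit_cell(7.90, 7.90, 3.80, laue_class = "4/mmm")
  expect_equal(sqrt(sum(reciprocal_basis(tet)[, 3]^2)), 1 / 3.80,
               tolerance = 1e-12)
  # duality B = A^-T for a skew cell
  mono <- unit_cell(7.28, 4.10, 16.77, beta = 99.4, laue_class = "2/m")
  A <- direct_basis(mono)
  expect_equal(unname(t(reciprocal_basis(mono)) %*% A), diag(3),
               tolerance = 1e-10)
})

test_that("family generation partitions the in-resolution reflections", {
  cell <- unit_cell(1, 1, 1, laue_class = "m-3m")
  fams <- generate_families(cell, 0.9)
  # only the {100} orbit is within 1/0.9 nm^-1 (|110| = 1.414 exceeds it)
  expect_equal(nrow(fams$families), 1L)
  expect_equal(fams$families$multiplicity, 6L)
  expect_equal(nrow(fams$hkl), 6L)
  expect_equal(sort(fams$mag), rep(1, 6), tolerance = 1e-12)
  expect_equal(fams$families[1, c("h", "k", "l")],
               data.frame(h = 1L, k = 0L, l = 0L), ignore_attr = TRUE)

  # huge d_min: nothing in resolution
  expect_equal(nrow(generate_families(cell, 1e6)$families), 0L)

  # partition property on a denser toy set
  fams <- generate_families(cell, 0.35)
  B <- reciprocal_basis(cell)
  grid <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
  inres <- grid[sqrt(rowSums((grid %*% t(B))^2)) <= 1 / 0.35 &
                  rowSums(abs(grid)) > 0, ]
  expect_equal(nrow(fams$hkl), nrow(inres))
  expect_setequal(paste(fams$hkl[, 1], fams$hkl[, 2], fams$hkl[, 3]),
                  paste(inres[, 1], inres[, 2], inres[, 3]))
  expect_false(any(duplicated(paste(fams$hkl[, 1], fams$hkl[, 2],
                                    fams$hkl[, 3]))))
  # members of one family share |h| to 1e-10 relative and d = 1/|h|
  for (f in unique(fams$family)) {
    m <- fams$mag[fams$family == f]
    expect_lt(diff(range(m)) / m[1], 1e-10)
  }
  expect_equal(fams$families$d, 1 / fams$families$mag, tolerance = 1e-12)
  # families sorted by |h| ascending
  expect_true(!is.unsorted(fams$families$mag))
})

test_that("triples related by a Laue operator land in the same family", {
  cell <- unit_cell(7.90, 7.90, 3.80, laue_class = "4/mmm")
  fams <- generate_families(cell, 0.8)
  key <- paste(fams$hkl[, 1], fams$hkl[, 2], fams$hkl[, 3])
  fam_of <- function(h) fams$family[match(paste(h[1], h[2], h[3]), key)]
  # 4-fold about c maps (h,k,l) -> (-k,h,l); Friedel mate -h too
  expect_equal(fam_of(c(2, 1, 1)), fam_of(c(-1, 2, 1)))
  expect_equal(fam_of(c(2, 1, 1)), fam_of(c(-2, -1, -1)))
  # but not unrelated triples of similar magnitude
  expect_false(fam_of(c(2, 1, 1)) == fam_of(c(1, 1, 2)))
})

test_that("centering filters remove forbidden reflections", {
  icell <- unit_cell(2, 2, 2, laue_class = "m-3m", centering = "I")
  fams <- generate_families(icell, 0.9)
  expect_true(all((rowSums(fams$hkl) %% 2) == 0))
  ccell <- unit_cell(7.28, 4.10, 16.77, beta = 99.4, laue_class = "2/m",
                     centering = "C")
  fams <- generate_families(ccell, 1.5)
  expect_true(all((fams$hkl[, 1] + fams$hkl[, 2]) %% 2 == 0))
})

test_that("family cap triggers an informative error", {
  cell <- unit_cell(6.39, 6.39, 6.39, laue_class = "m-3m")
  expect_error(generate_families(cell, 0.2, max_families = 10), "d_min")
})

test_that("family TSV export writes the documented columns", {
  fams <- generate_families(unit_cell(1, 1, 1, laue_class = "m-3m"), 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_families(fams, path)
  tab <- read.delim(path)
  expect_named(tab, c("h", "k", "l", "mag", "d", "multiplicity"))
  expect_equal(nrow(tab), nrow(fams$families))
})
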