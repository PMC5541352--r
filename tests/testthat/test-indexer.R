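# Candidate pairing, matching, refinement, acceptance, and the assembled
# pipeline on the fast toy crystal.

test_that("magnitude pairing matches an exhaustive oracle", {
  cell <- unit_cell(1, 1, 1, laue_class = "m-3m")
  geom <- beam_geometry(wavelength = 0.1, distance = 0.1)
  params <- felix_params(n_voxels = 10, d_min = 0.45, sigma = 0.2,
                         sigma_2theta = 0.5)
  fams <- generate_families(cell, 0.45)
  set.seed(41)
  G <- rbind(c(1, 0.02, 0), c(0, 1.41, 0.05), c(0.4, 0.4, 0.4))
  pairs <- build_candidate_pairs(G, fams, params, geom)
  # oracle: brute-force filter over every reflection
  lam <- geom$wavelength
  for (gi in 1:nrow(G)) {
    gm <- sqrt(sum(G[gi, ]^2))
    theta <- asin(gm * lam / 2)
    tol <- params$sigma * (params$sigma_2theta * pi / 180 / 2) / tan(theta)
    want <- which(abs(gm - fams$mag) / fams$mag <= tol)
    got <- pairs$member_index[pairs$g_index == gi]
    expect_setequal(got, want)
  }
})

test_that("pairing keeps exact magnitudes and drops gross mismatches", {
  cell <- unit_cell(1, 1, 1, laue_class = "m-3m")
  geom <- beam_geometry(wavelength = 0.1, distance = 0.1)
  fams <- generate_families(cell, 0.9)      # single family, |h| = 1
  params <- felix_params(n_voxels = 10, d_min = 0.9, sigma = 1,
                         sigma_2theta = 0.573)  # ~0.005 rad half-width
  # exact match accepted at any positive tolerance
  p <- build_candidate_pairs(rbind(c(1, 0, 0)), fams, params, geom)
  expect_gt(length(p$g_index), 0)
  # 10% off with ~5% total tolerance: rejected
  p <- build_candidate_pairs(rbind(c(1.1, 0, 0)), fams, params, geom)
  expect_length(p$g_index, 0)
})

test_that("g vectors generated from the lattice match with zero deviation", {
  scn <- toy_scenario()
  set.seed(42)
  fams <- generate_families(scn$cell, scn$params$d_min)
  q <- random_orientation(1)[1, ]
  sp <- predict_spots(q, scn$cell, scn$geom, scn$params$d_min,
                      scn$params$r_profile, families = fams)
  G <- unname(cbind(sp$gx, sp$gy, sp$gz))   # exact reciprocal points
  m <- match_gvectors(q, G, fams, scn$params, geom = scn$geom)
  expect_equal(nrow(m), nrow(sp))
  # deviations at acos() rounding level (~1e-8 rad) for exact inputs
  expect_lt(max(m$deviation), 1e-5)
  # ground-truth hkl recovered
  expect_equal(m[order(m$g_index), c("h", "k", "l")],
               sp[, c("h", "k", "l")], ignore_attr = TRUE)
  # no double assignment in either direction
  expect_false(any(duplicated(m$g_index)))
  expect_false(any(duplicated(m$member_index)))

  # rotating the observations far from every prediction kills all matches
  Roff <- quat_to_matrix(quat_from_axis_angle(c(0, 0, 1), 5 * pi / 180))
  m2 <- match_gvectors(q, G %*% t(Roff), fams, scn$params, geom = scn$geom,
                       tol_deg = 0.5)
  expect_lt(nrow(m2), max(1, nrow(sp) * 0.2))
})

test_that("refinement recovers a perturbed orientation to high accuracy", {
  scn <- toy_scenario()
  set.seed(43)
  fams <- generate_families(scn$cell, scn$params$d_min)
  q <- random_orientation(1)[1, ]
  sp <- predict_spots(q, scn$cell, scn$geom, scn$params$d_min,
                      scn$params$r_profile, families = fams)
  G <- unname(cbind(sp$gx, sp$gy, sp$gz))
  seed_q <- quat_canonical(quat_multiply(
    quat_from_axis_angle(rnorm(3), 1 * pi / 180), q))
  m <- match_gvectors(seed_q, G, fams, scn$params, geom = scn$geom,
                      tol_deg = 3)
  r <- refine_orientation(seed_q, m, G, fams, scn$params)
  expect_false(is.null(r))
  mis <- misorientation(r$q, q, laue_operators("m-3m"))
  expect_lt(mis$angle, 0.01)
})

test_that("a planted outlier is trimmed while good matches survive", {
  scn <- toy_scenario()
  set.seed(44)
  fams <- generate_families(scn$cell, scn$params$d_min)
  q <- random_orientation(1)[1, ]
  sp <- predict_spots(q, scn$cell, scn$geom, scn$params$d_min,
                      scn$params$r_profile, families = fams)
  G <- unname(cbind(sp$gx, sp$gy, sp$gz))
  m <- match_gvectors(q, G, fams, scn$params, geom = scn$geom)
  # corrupt one observation by 10 degrees after matching
  bad <- m$g_index[1]
  Rbad <- quat_to_matrix(quat_from_axis_angle(c(1, 1, 0), 10 * pi / 180))
  G[bad, ] <- G[bad, ] %*% t(Rbad)
  r <- refine_orientation(q, m, G, fams, scn$params)
  expect_false(bad %in% r$matched$g_index)
  expect_equal(nrow(r$matched), nrow(m) - 1)
  mis <- misorientation(r$q, q, laue_operators("m-3m"))
  expect_lt(mis$angle, 0.01)
})

test_that("refinement is underdetermined with too few or collinear matches", {
  scn <- toy_scenario()
  fams <- generate_families(scn$cell, scn$params$d_min)
  one <- data.frame(g_index = 1L, member_index = 1L, h = fams$hkl[1, 1],
                    k = fams$hkl[1, 2], l = fams$hkl[1, 3], deviation = 0)
  G <- matrix(c(1, 0, 0), 1, 3)
  expect_null(refine_orientation(c(1, 0, 0, 0), one, G, fams, scn$params))
  # two collinear matches (a reflection and its Friedel mate)
  i1 <- 1L
  hv <- fams$hvec[i1, ]
  i2 <- which(apply(fams$hvec, 1, function(v) all(abs(v + hv) < 1e-12)))[1]
  two <- data.frame(g_index = c(1L, 2L), member_index = c(i1, i2),
                    h = fams$hkl[c(i1, i2), 1], k = fams$hkl[c(i1, i2), 2],
                    l = fams$hkl[c(i1, i2), 3], deviation = 0)
  G2 <- rbind(hv, -hv)
  expect_null(refine_orientation(c(1, 0, 0, 0), two, G2, fams, scn$params))
})

test_that("acceptance enforces count, completeness and uniqueness", {
  params <- felix_params(n_voxels = 10, d_min = 0.5, n_min = 10,
                         c_min = 0.5, u_max = 0.5)
  mk <- function(n, gset, comp, visits = 1) {
    list(q = c(1, 0, 0, 0), U = diag(3),
         matched = data.frame(g_index = gset), n_matched = n,
         completeness = comp, visits = visits)
  }
  a <- mk(20, 1:20, 0.9)
  # duplicate candidates: one survives
  out <- accept_solutions(list(a, a), params)
  expect_length(out, 1)
  # low completeness rejected
  out <- accept_solutions(list(a, mk(20, 21:40, 0.4)), params)
  expect_length(out, 1)
  # below n_min rejected
  out <- accept_solutions(list(a, mk(5, 41:45, 0.9)), params)
  expect_length(out, 1)
  # disjoint solutions both kept, ordered by match count
  b <- mk(30, 101:130, 0.8)
  out <- accept_solutions(list(a, b), params)
  expect_length(out, 2)
  expect_equal(out[[1]]$n_matched, 30)
  # partial overlap beyond u_max drops the weaker candidate
  c1 <- mk(15, 1:15, 0.9)
  out <- accept_solutions(list(a, c1), params)
  expect_length(out, 1)
})

test_that("loosening n_min or c_min never loses accepted solutions", {
  scn <- toy_scenario()
  set.seed(45)
  fams <- generate_families(scn$cell, scn$params$d_min)
  img <- simulate_image(3, scn, families = fams)
  counts <- c()
  for (spec in list(c(12, 0.8), c(8, 0.5), c(4, 0.2))) {
    p <- scn$params
    p$n_min <- spec[1]; p$c_min <- spec[2]
    res <- index_image(img$peaks, scn$cell, scn$geom, p, families = fams)
    counts <- c(counts, length(res$solutions))
  }
  expect_true(all(diff(counts) >= 0))
})

test_that("the toy pipeline recovers single crystals and is deterministic", {
  scn <- toy_scenario()
  fams <- generate_families(scn$cell, scn$params$d_min)
  acc <- frustum_accumulator(scn$params$n_voxels)
  ops <- laue_operators("m-3m")
  set.seed(46)
  for (rep in 1:5) {
    img <- simulate_image(1, scn, families = fams)
    res <- index_image(img$peaks, scn$cell, scn$geom, scn$params,
                       families = fams, acc = acc)
    expect_gte(length(res$solutions), 1)
    mis <- misorientation(res$solutions[[1]]$q, img$orientations[1, ], ops)
    expect_lt(mis$angle, 0.2)
    # matched peaks exist and are uniquely assigned
    m <- res$solutions[[1]]$matched
    expect_true(all(m$g_index %in% seq_len(nrow(img$peaks))))
    expect_false(any(duplicated(m$g_index)))
    # byte-identical rerun
    res2 <- index_image(img$peaks, scn$cell, scn$geom, scn$params,
                        families = fams, acc = acc)
    expect_identical(res, res2)
  }
})

test_that("empty input gives an empty solution list", {
  scn <- toy_scenario()
  res <- index_image(data.frame(x_m = numeric(), y_m = numeric()),
                     scn$cell, scn$geom, scn$params)
  expect_length(res$solutions, 0)
  expect_equal(res$n_peaks, 0L)
})

test_that("multi-crystal toy images are resolved into separate lattices", {
  scn <- toy_scenario()
  fams <- generate_families(scn$cell, scn$params$d_min)
  acc <- frustum_accumulator(scn$params$n_voxels)
  ops <- laue_operators("m-3m")
  set.seed(47)
  found <- 0; correct <- 0; ntrue <- 0
  for (rep in 1:3) {
    img <- simulate_image(5, scn, families = fams)
    res <- index_image(img$peaks, scn$cell, scn$geom, scn$params,
                       families = fams, acc = acc)
    rep_acc <- match_to_truth(list(res), list(img$orientations),
                              tolerance_deg = 1, laue_ops = ops)
    found <- found + sum(rep_acc$per_image$n_found)
    correct <- correct + sum(rep_acc$per_image$n_correct)
    ntrue <- ntrue + 5
  }
  expect_gte(correct / ntrue, 0.8)     # recall on easy noise-free images
  expect_gte(correct / found, 0.8)     # precision
})
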