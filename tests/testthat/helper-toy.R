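# Small fast fixtures used across the test files.

# A low-resolution cubic crystal and matching indexer settings: few
# reflections and a coarse orientation grid, so full pipeline runs finish in
# well under a second.
toy_scenario <- function(n_voxels = 60, ...) {
  cell <- unit_cell(5.0, 5.0, 5.0, laue_class = "m-3m")
  geom <- beam_geometry(wavelength = 0.1, distance = 0.1)
  params <- felix_params(n_voxels = n_voxels, v_min = 5, f_v = 0.5,
                         sigma_2theta = 0.6, sigma_eta = 0.6,
                         n_min = 6, d_min = 0.5, ...)
  custom_scenario(cell, geom, params, name = "toy-cubic")
}

# rotation matrix applied to the columns of a 3 x n matrix
rot_apply <- function(q, v) quat_to_matrix(q) %*% v

expect_quat_equal <- function(q1, q2, tol = 1e-9) {
  q1 <- quat_canonical(q1); q2 <- quat_canonical(q2)
  expect_lt(min(sum((q1 - q2)^2), sum((q1 + q2)^2)), tol^2)
}

# independent misorientation oracle via rotation matrices and traces: a lab
# rotation R maps lattice 1 onto lattice 2 iff R = U2 S U1^T for a crystal
# symmetry S, and angle(U2 S U1^T) = angle(S U1^T U2) by cyclic invariance
misang_matrix_oracle <- function(q1, q2, ops) {
  M <- t(quat_to_matrix(q1)) %*% quat_to_matrix(q2)
  best <- Inf
  for (S in ops) {
    tr <- sum(diag(S %*% M))
    best <- min(best, acos(pmin(1, pmax(-1, (tr - 1) / 2))))
  }
  best * 180 / pi
}
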