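test_that("registry lookups and structural contracts", {
  expect_error(discovered_algorithm("C99Tri"), "unregistered")

  g <- make_uniform_grid(-5, 5, 31)
  set.seed(61)
  pes <- sample_bound_polynomial()
  V <- evaluate_pes(pes, g$points)

  Mtri <- build_matrix("C20Tri_E1_A", V, g)
  expect_lte(count_nonzeros(Mtri)$count, 3 * 31 - 2)

  # the potential enters the diagonal additively
  M2 <- build_matrix("C20Tri_E1_A", V + 4, g)
  expect_equal(diag(M2) - diag(Mtri), rep(4, 31))
  expect_equal(M2 - diag(4, 31), Mtri, ignore_attr = TRUE)

  for (lab in c("C15Full_E1_A", "C20Full_E1_A", "C25Full_E1_A")) {
    M <- build_matrix(lab, V, g)
    expect_identical(M, t(M))
  }
})

test_that("tridiagonal-rule eigenvectors overlap the converged oracle", {
  set.seed(62)
  pes <- sample_bound_polynomial()
  gc <- make_uniform_grid(-5, 5, 51)
  go <- make_uniform_grid(-5, 5, 151)
  Vc <- evaluate_pes(pes, gc$points)
  Vo <- evaluate_pes(pes, go$points)
  sol <- solve_lowest(build_matrix("C20Tri_E1_A", Vc, gc), 3)
  oracle <- solve_lowest(cmdvr_hamiltonian_1d(Vo, go), 3)
  idx <- nearest_index_map(gc, go)
  for (k in 1:3) {
    ref <- oracle$vectors[idx, k]
    ref <- ref / sqrt(sum(ref^2))
    expect_gt(abs(sum(sol$vectors[, k] * ref)), 0.999)
  }
})

test_that("solving returns expectation energies and refuses the eigenvalue route", {
  g <- make_uniform_grid(-5, 5, 101)
  V <- g$points^2 / 2
  sol <- solve_discovered("C20Tri_E1_A", V, g, n_e = 3)
  expect_lt(max(abs(sol$energies - c(0.5, 1.5, 2.5)) / c(0.5, 1.5, 2.5)),
            0.01)
  expect_error(solve_discovered("C20Tri_E1_A", V, g,
                                energy_mode = "eigenvalue"),
               "not energies")

  # C25Full doubles the spectrum but keeps the eigenvectors: the textbook
  # example of why matrix eigenvalues of discovered codes are not energies
  set.seed(63)
  pes <- sample_bound_polynomial()
  g41 <- make_uniform_grid(-5, 5, 41)
  V41 <- evaluate_pes(pes, g41$points)
  scm <- solve_lowest(cmdvr_hamiltonian_1d(V41, g41), 3)
  s25 <- solve_lowest(build_matrix("C25Full_E1_A", V41, g41), 3)
  expect_equal(s25$values, 2 * scm$values, tolerance = 1e-9)
  for (k in 1:3)
    expect_gt(abs(sum(s25$vectors[, k] * scm$vectors[, k])), 1 - 1e-9)

  # six states, ascending
  s6 <- solve_discovered("C20Tri_E1_A", V, g, n_e = 6)
  expect_length(s6$energies, 6)
  expect_true(all(diff(s6$energies) > 0))
})

test_that("2-D double-well eigenvectors from the tridiagonal assembly match CM-DVR", {
  g <- make_uniform_grid(-5, 5, 41)
  pes <- model_pes("double_well_2d")
  scm <- solve_dvr("cmdvr", pes, list(g, g), n_e = 4)
  stri <- solve_discovered("C20Tri_E1_A", pes, list(g, g), n_e = 4)
  # the fourth state: same nodal structure, overlap after sign alignment
  expect_gt(abs(sum(scm$vectors[, 4] * stri$vectors[, 4])), 0.99)
})

test_that("tridiagonal-rule accuracy tracks grids and dominates FD", {
  sw <- convergence_sweep(c("cmdvr", "fd", "C20Tri_E1_A"),
                          ng_list = c(21, 41, 61, 81), n_test = 20,
                          seed = 64)
  tri <- sw[sw$solver == "C20Tri_E1_A", ]
  fd <- sw[sw$solver == "fd", ]
  # expectation-route energies of the sparse rule beat the FD eigenvalues
  # by a wide margin at every grid size, and errors shrink with n_g
  expect_true(all(tri$E_f < fd$E_f / 3))
  expect_lt(tri$E_f[tri$n_g == 81], tri$E_f[tri$n_g == 21])
  expect_lt(max(tri$E_f), 3e-2)
})

test_that("states 4-6 stay within the published accuracy regime", {
  # under the energy-zero convention the 3-state errors sit at the
  # quadrature noise floor, so a ratio test against them is vacuous; the
  # substantive claim is that the six-state error remains far below the
  # 3e-2 published test-set error and keeps converging with grid size
  r6 <- vapply(c(21, 41), function(ng) {
    set.seed(65)
    ts <- generate_target_set(M = 25, n_e = 6, grid_mode = "fixed",
                              ng_fixed = ng)
    pred <- predict_with_builder(ts, build_discovered("C20Tri_E1_A"), 6)
    rms(fractional_errors(pred, ts, 6)$delta)
  }, numeric(1))
  expect_true(all(r6 < 3e-2))
  expect_lt(r6[2], r6[1])
})
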