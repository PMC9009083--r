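test_that("sign alignment maximises the inner product with +1 tie rule", {
  psi <- c(1, 2, 3) / sqrt(14)
  expect_equal(align_sign(-psi, psi), list(S = -1, aligned = psi))
  expect_equal(align_sign(psi, psi)$S, 1)
  expect_equal(align_sign(c(0, 0, 1), c(1, 0, 0))$S, 1)  # orthogonal tie
})

test_that("nearest-point resampling matches a brute-force oracle", {
  fine <- make_uniform_grid(-5, 5, 151)
  same <- nearest_index_map(fine, fine)
  expect_identical(same, seq_len(151))

  coarse <- make_uniform_grid(-5, 5, 15)
  expect_identical(nearest_index_map(coarse, fine),
                   brute_nearest(coarse$points, fine$points))

  # exact midpoint resolves to the lower fine index
  f2 <- make_uniform_grid(0, 1, 3)     # 0, 0.5, 1
  c2 <- make_uniform_grid(0.25, 0.75, 3)
  expect_identical(nearest_index_map(c2, f2)[1], 1L)

  vals <- sin(fine$points)
  expect_equal(resample_to_target(vals, coarse, fine),
               vals[brute_nearest(coarse$points, fine$points)])
})

test_that("wavefunction cost is zero iff exact up to sign, with hand value", {
  g <- make_uniform_grid(-1, 1, 3)
  psi <- matrix(c(1, 0, 0), ncol = 1)
  ts <- fake_target_set(g, numeric(3), psi, 1, n_e = 1)

  pred_exact <- list(list(failed = FALSE, values = 1, vectors = psi))
  expect_equal(wavefunction_cost(pred_exact, ts)$F, 0)
  pred_flip <- list(list(failed = FALSE, values = 1, vectors = -psi))
  expect_equal(wavefunction_cost(pred_flip, ts)$F, 0)

  pred_off <- list(list(failed = FALSE, values = 1,
                        vectors = matrix(c(0, 1, 0), ncol = 1)))
  expect_equal(wavefunction_cost(pred_off, ts)$F, sqrt(2 / 3))

  # failed prediction -> worst-case cost
  expect_equal(wavefunction_cost(list(list(failed = TRUE)), ts)$F, Inf)
})

test_that("energy costs implement the RMS fractional error with components", {
  g <- make_uniform_grid(-1, 1, 3)
  psi <- cbind(c(1, 0, 0), c(0, 1, 0))
  ts <- fake_target_set(g, numeric(3), psi, c(1, 2), n_e = 2)

  # eigenvalue route, hand value: E = (1.1, 1.8) vs (1, 2) -> RMS 0.1
  pred <- list(list(failed = FALSE, values = c(1.1, 1.8), vectors = psi))
  r <- e2_cost(pred, ts)
  expect_equal(r$components[["energy"]], 0.1, tolerance = 1e-12)
  expect_equal(r$components[["wavefunction"]], 0)
  expect_equal(r$F, sum(r$components))

  # scale invariance of the fractional error
  ts2 <- fake_target_set(g, numeric(3), psi, c(2, 4), n_e = 2)
  pred2 <- list(list(failed = FALSE, values = c(2.2, 3.6), vectors = psi))
  expect_equal(e2_cost(pred2, ts2)$components[["energy"]], 0.1,
               tolerance = 1e-12)

  # perfect eigenpairs -> zero composite cost
  pred3 <- list(list(failed = FALSE, values = c(1, 2), vectors = psi))
  expect_equal(e2_cost(pred3, ts)$F, 0)

  # lambda = 2 * Etilde -> energy component exactly 1
  pred4 <- list(list(failed = FALSE, values = c(2, 4), vectors = psi))
  expect_equal(e2_cost(pred4, ts)$components[["energy"]], 1)

  # near-zero oracle energies are excluded with a warning
  ts3 <- fake_target_set(g, numeric(3), psi, c(0, 2), n_e = 2)
  expect_warning(r3 <- e2_cost(pred3, ts3), "excluded")
})

test_that("e1 cost of the oracle itself is bounded by quadrature error", {
  set.seed(77)
  ts <- generate_target_set(M = 4, n_e = 3, grid_mode = "fixed",
                            ng_fixed = 151)
  pred <- lapply(ts$problems, function(p) {
    list(failed = FALSE, values = p$targets$energies,
         vectors = p$targets$psi)
  })
  expect_lt(e1_cost(pred, ts)$F, 2e-3)
})

test_that("cost invariance under predicted-vector sign flips", {
  set.seed(14)
  ts <- generate_target_set(M = 3, n_e = 2)
  pred <- predict_with_builder(ts, function(V, g, m) cmdvr_hamiltonian_1d(V, g, m),
                               n_e = 2)
  flipped <- lapply(pred, function(p) {
    p$vectors <- -p$vectors; p
  })
  expect_equal(wavefunction_cost(pred, ts, 2)$F,
               wavefunction_cost(flipped, ts, 2)$F, tolerance = 1e-12)
  expect_equal(e1_cost(pred, ts, 2)$F, e1_cost(flipped, ts, 2)$F,
               tolerance = 1e-12)
})

test_that("fractional error distribution is consistent with the e1 cost", {
  set.seed(55)
  ts <- generate_target_set(M = 10, n_e = 3, grid_mode = "fixed",
                            ng_fixed = 91)
  solver <- function(problem, n_e) {
    sol <- solve_lowest(cmdvr_hamiltonian_1d(problem$V, problem$grid,
                                             problem$m), n_e)
    list(failed = FALSE, values = sol$values, vectors = sol$vectors)
  }
  d <- fractional_error_distribution(solver, ts)
  # definitional consistency with the cost function
  pred <- lapply(ts$problems, solver, n_e = 3)
  expect_equal(d$rms, e1_cost(pred, ts)$F, tolerance = 1e-12)
  # CM-DVR at n_g = 91 against the 151-point oracle is well converged
  expect_lt(d$rms, 1e-3)

  # a perfect 'algorithm' (oracle replayed on the oracle grid) -> ~0
  ts2 <- generate_target_set(M = 2, n_e = 2, grid_mode = "fixed",
                             ng_fixed = 151)
  pred2 <- lapply(ts2$problems, function(p)
    list(failed = FALSE, values = p$targets$energies, vectors = p$targets$psi))
  fr <- fractional_errors(pred2, ts2, 2, energy_from = "eigenvalue")
  expect_equal(fr$delta, rep(0, 4))
})
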