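test_that("Colbert-Miller Hamiltonian reproduces the harmonic spectrum", {
  hp <- ho_problem(101, c(-7, 7))
  H <- cmdvr_hamiltonian_1d(hp$V, hp$grid)
  expect_identical(H, t(H))   # exact symmetry by construction

  sol <- solve_lowest(H, 3)
  expect_lt(max(abs(sol$values - c(0.5, 1.5, 2.5))), 1e-8)

  # residual and normalisation contracts
  Hm <- H
  for (k in 1:3) {
    v <- sol$vectors[, k]
    expect_equal(sum(v^2), 1, tolerance = 1e-10)
    expect_lt(sqrt(sum((Hm %*% v - sol$values[k] * v)^2)), 1e-8 * norm(Hm, "2"))
  }

  # constant shift moves eigenvalues, not eigenvectors
  sol2 <- solve_lowest(cmdvr_hamiltonian_1d(hp$V + 3.2, hp$grid), 3)
  expect_equal(sol2$values, sol$values + 3.2, tolerance = 1e-9)
  for (k in 1:3)
    expect_gt(abs(sum(sol2$vectors[, k] * sol$vectors[, k])), 1 - 1e-10)

  expect_error(cmdvr_hamiltonian_1d(numeric(5), hp$grid), "does not match")
})

test_that("harmonic-oscillator convergence is monotone down to the arithmetic floor", {
  # sinc-DVR convergence is exponential: between adjacent rungs of this
  # ladder the error crosses the double-precision floor, below which
  # rounding noise dominates.  Assert strict decrease until the floor and
  # floor-level errors thereafter.
  errs <- vapply(c(21, 41, 81, 151), function(n) {
    hp <- ho_problem(n, c(-12, 12))
    sol <- solve_lowest(cmdvr_hamiltonian_1d(hp$V, hp$grid), 3)
    max(abs(sol$values - c(0.5, 1.5, 2.5)))
  }, numeric(1))
  floor_tol <- 1e-12
  for (i in seq_along(errs)[-1])
    expect_true(errs[i] < errs[i - 1] ||
                (errs[i] < floor_tol && errs[i - 1] < floor_tol))
  expect_lt(errs[4], floor_tol)
})

test_that("finite-difference Hamiltonian is tridiagonal with known limits", {
  hp <- ho_problem(101, c(-5, 5))
  Hfd <- fd_hamiltonian_1d(hp$V, hp$grid)
  expect_equal(count_nonzeros(Hfd)$count, 3 * 101 - 2)

  efd <- solve_lowest(Hfd, 1)$values
  ecm <- solve_lowest(cmdvr_hamiltonian_1d(hp$V, hp$grid), 1)$values
  expect_lt(abs(efd - 0.5), 0.01)            # O(dx^2) ballpark
  expect_gt(abs(efd - 0.5), abs(ecm - 0.5))  # CM-DVR strictly better

  # V = 0: Toeplitz tridiagonal with closed-form spectrum
  n <- 40
  g <- make_uniform_grid(0, 1, n)
  a <- 1 / (2 * g$dx^2)
  T0 <- fd_hamiltonian_1d(numeric(n), g)
  lam <- sort(2 * a - 2 * a * cos(seq_len(n) * pi / (n + 1)))
  expect_equal(solve_lowest(T0, n - 1)$values, lam[1:(n - 1)],
               tolerance = 1e-10)
})

test_that("1-D spectra are invariant under coordinate reversal", {
  set.seed(31)
  pes <- sample_bound_polynomial()
  g <- make_uniform_grid(-5, 5, 41)
  V <- evaluate_pes(pes, g$points)
  for (builder in list(cmdvr_hamiltonian_1d, fd_hamiltonian_1d)) {
    e1 <- solve_lowest(builder(V, g), 4)$values
    e2 <- solve_lowest(builder(rev(V), g), 4)$values
    expect_equal(e1, e2, tolerance = 1e-9)
  }
})

test_that("direct-product assembly matches Kronecker-sum structure", {
  g5 <- make_uniform_grid(-5, 5, 5)
  ktri <- build_matrix("C20Tri_E1_A", numeric(5), g5)
  kcm <- cmdvr_hamiltonian_1d(numeric(5), g5)

  expect_equal(count_nonzeros(
    assemble_direct_product(list(ktri, ktri), numeric(25)))$count,
    5 * 5^2 - 4 * 5)
  expect_equal(count_nonzeros(
    assemble_direct_product(list(kcm, kcm), numeric(25)))$count,
    2 * 5^3 - 5^2)

  # f = 1 reduces to the 1-D matrix exactly
  V <- runif(5)
  H1 <- assemble_direct_product(list(kcm), V)
  expect_equal(as.matrix(H1), kcm + diag(V), ignore_attr = TRUE)

  # numerical agreement with a dense base-R construction
  Vm <- runif(25)
  H2 <- assemble_direct_product(list(ktri, kcm), Vm)
  dense <- kronecker(ktri, diag(5)) + kronecker(diag(5), kcm) + diag(Vm)
  expect_equal(as.matrix(H2), dense, ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(assemble_direct_product(list(ktri), numeric(7)), "length")
})

test_that("solve_lowest agrees across dense and sparse paths", {
  expect_equal(solve_lowest(diag(c(1, 2, 3)), 1)$values, 1)
  expect_equal(abs(solve_lowest(diag(c(1, 2, 3)), 1)$vectors[, 1]),
               c(1, 0, 0))

  ones <- matrix(1, 3, 3)
  expect_equal(solve_lowest(ones, 3)$values, c(0, 0, 3), tolerance = 1e-12)

  set.seed(5)
  A <- matrix(rnorm(2500), 50, 50)
  A <- (A + t(A)) / 2
  d <- solve_lowest(A, 3, method = "dense")
  s <- solve_lowest(Matrix::Matrix(A, sparse = TRUE), 3,
                    method = "sparse_iterative")
  expect_lt(max(abs(d$values - s$values)), 1e-8)
  for (k in 1:3)
    expect_gt(abs(sum(d$vectors[, k] * s$vectors[, k])), 1 - 1e-8)

  expect_error(solve_lowest(diag(3), 4), "must not exceed")
  expect_error(solve_lowest(Matrix::Matrix(diag(3), sparse = TRUE), 3,
                            method = "sparse_iterative"), "strictly smaller")
})

test_that("nonzero counting matches closed forms and brute force", {
  g <- make_uniform_grid(-5, 5, 91)
  expect_equal(count_nonzeros(fd_hamiltonian_1d(numeric(91), g))$count,
               271)
  expect_equal(count_nonzeros(matrix(0, 8, 8))$count, 0)

  g11 <- make_uniform_grid(-5, 5, 11)
  ktri <- build_matrix("C20Tri_E1_A", numeric(11), g11)
  H3 <- assemble_direct_product(rep(list(ktri), 3), numeric(11^3))
  expect_equal(count_nonzeros(H3)$count, 7 * 11^3 - 6 * 11^2)  # 8591

  # tolerance invariance across [1e-12, 1e-10] for CM-DVR assemblies
  kcm <- cmdvr_hamiltonian_1d(numeric(11), g11)
  H2 <- assemble_direct_product(list(kcm, kcm), numeric(11^2))
  expect_equal(count_nonzeros(H2, 1e-12)$count,
               count_nonzeros(H2, 1e-10)$count)
})

test_that("MatrixMarket export round-trips a sparse assembly", {
  g <- make_uniform_grid(-5, 5, 5)
  ktri <- build_matrix("C20Tri_E1_A", numeric(5), g)
  H <- assemble_direct_product(list(ktri, ktri), runif(25))
  tmp <- withr::local_tempfile(fileext = ".mtx")
  write_matrix_market(H, tmp)
  back <- Matrix::readMM(tmp)
  expect_equal(as.matrix(back), as.matrix(H), tolerance = 1e-12,
               ignore_attr = TRUE)
})
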