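# shared fixtures and small independent oracles

rms <- function(x) sqrt(mean(x^2))

# harmonic oscillator V = x^2/2 tabulated on a grid
ho_problem <- function(n_g = 101, range = c(-7, 7), m = 1) {
  g <- make_uniform_grid(range[1], range[2], n_g)
  list(grid = g, V = g$points^2 / 2, m = m)
}

# a polynomial_pes with explicit scaled-coordinate coefficients
manual_poly <- function(coefficients, range = c(-5, 5)) {
  structure(list(coefficients = coefficients,
                 degree = length(coefficients), range = range,
                 rejections = 0L),
            class = c("polynomial_pes", "psdvr_pes"))
}

# brute-force nearest-fine-point index map (double loop, lower-index ties)
brute_nearest <- function(coarse, fine) {
  out <- integer(length(coarse))
  for (i in seq_along(coarse)) {
    d <- abs(fine - coarse[i])
    out[i] <- which(d == min(d))[1]
  }
  out
}

# brute-force structural nonzero count of an f-dimensional Kronecker-sum
# assembly, built with base kronecker on dense matrices
brute_kron_nnz <- function(K, f, tol = 1e-12) {
  n <- nrow(K)
  H <- matrix(0, n^f, n^f)
  for (k in seq_len(f)) {
    term <- K
    if (k > 1) term <- kronecker(diag(n^(k - 1)), term)
    if (k < f) term <- kronecker(term, diag(n^(f - k)))
    H <- H + term
  }
  sum(abs(H) > tol)
}

# predictions of a matrix-builder solver on every problem of a target set
predict_with_builder <- function(ts, builder, n_e = ts$n_e) {
  lapply(ts$problems, function(p) {
    sol <- solve_lowest(builder(p$V, p$grid, p$m), n_e)
    list(failed = FALSE, values = sol$values, vectors = sol$vectors)
  })
}

build_discovered <- function(label) {
  alg <- discovered_algorithm(label)
  function(V, grid, m) build_matrix(alg, V, grid, m)
}

# locate an internal library option by its manifest name
find_internal <- function(lib, name) {
  idx <- which(vapply(lib$internal_options, `[[`, "", "name") == name)
  stopifnot(length(idx) == 1)
  idx
}

# minimal hand-built target set around explicit oracle data
fake_target_set <- function(grid, V, psi, energies, n_e = ncol(psi), m = 1) {
  problem <- structure(
    list(grid = grid, V = V, m = m, pes = NULL,
         targets = list(grid = grid, psi = psi, energies = energies)),
    class = "target_problem")
  structure(list(problems = list(problem), n_e = n_e, m = m,
                 grid_mode = "fixed", oracle_n_g = grid$n_g),
            class = "target_set")
}
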