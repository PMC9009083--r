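#' Colbert-Miller DVR Hamiltonian (1-D)
#'
#' Dense symmetric Hamiltonian for a particle of mass `m` on a uniform grid:
#' the potential sits on the diagonal and the sinc-DVR kinetic operator
#' contributes `pi^2/3 / (2 m dx^2)` on the diagonal and
#' `(-1)^(i-j) * 2/(i-j)^2 / (2 m dx^2)` off the diagonal, so the kinetic
#' coupling decays as `1/(i-j)^2`.  Convergence with grid size is
#' exponential for smooth bound potentials, which is why this operator also
#' serves as the package's reference ("oracle") solver.
#'
#' @param V Potential values on the grid (`length(V) == grid$n_g`).
#' @param grid A [make_uniform_grid()] grid.
#' @param m Particle mass (default 1).
#' @return A dense symmetric `n_g x n_g` matrix with attribute
#'   `source = "cmdvr"`.
#' @export
cmdvr_hamiltonian_1d <- function(V, grid, m = 1) {
  check_V_grid(V, grid)
  n <- grid$n_g
  idx <- seq_len(n)
  d <- outer(idx, idx, "-")
  Tm <- matrix(0, n, n)
  off <- d != 0
  Tm[off] <- 2 * (-1)^d[off] / d[off]^2
  diag(Tm) <- pi^2 / 3
  H <- Tm / (2 * m * grid$dx^2) + diag(V, n)
  attr(H, "source") <- "cmdvr"
  H
}

#' Central finite-difference DVR Hamiltonian (1-D)
#'
#' Exactly tridiagonal Hamiltonian with the 3-point central-difference
#' kinetic operator: diagonal `V_i + 1/(m dx^2)`, first off-diagonals
#' `-1/(2 m dx^2)`.  Second-order accurate in `dx`; at equal grid size its
#' eigenvalues are markedly less accurate than Colbert-Miller's.
#'
#' @inheritParams cmdvr_hamiltonian_1d
#' @return A dense symmetric tridiagonal matrix with attribute
#'   `source = "fd"`.
#' @export
fd_hamiltonian_1d <- function(V, grid, m = 1) {
  check_V_grid(V, grid)
  n <- grid$n_g
  a <- 1 / (2 * m * grid$dx^2)
  H <- diag(V + 2 * a, n)
  H[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- -a
  H[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- -a
  attr(H, "source") <- "fd"
  H
}

check_V_grid <- function(V, grid) {
  stopifnot(is_grid(grid))
  if (length(V) != grid$n_g)
    stop("length(V) = ", length(V), " does not match grid$n_g = ", grid$n_g)
  invisible(TRUE)
}

#' Direct-product (Kronecker-sum) multidimensional Hamiltonian
#'
#' Assemble an f-dimensional grid Hamiltonian from per-dimension 1-D
#' *kinetic-like* matrices `K^(k)` (a 1-D solver matrix with its diagonal
#' potential removed) and the multidimensional potential tabulated on the
#' direct-product grid:
#' `H = sum_k I x ... x K^(k) x ... x I + diag(V_multi)`.
#' Ordering is row-major with the first coordinate slowest, matching
#' [evaluate_pes_on_grid()].
#'
#' @param kinetic_parts List of `f` square matrices (dense or sparse), one
#'   per dimension, with their 1-D potential already removed.
#' @param V_multi Potential on the direct-product grid,
#'   `length(V_multi) == prod(sizes)`.
#' @return A symmetric sparse `Matrix::dgCMatrix` with attribute `dims = f`.
#' @export
assemble_direct_product <- function(kinetic_parts, V_multi) {
  stopifnot(length(kinetic_parts) >= 1)
  sizes <- vapply(kinetic_parts, nrow, integer(1))
  if (any(sizes != vapply(kinetic_parts, ncol, integer(1))))
    stop("kinetic parts must be square")
  ntot <- prod(sizes)
  if (length(V_multi) != ntot)
    stop("V_multi has length ", length(V_multi), ", expected ", ntot)
  f <- length(kinetic_parts)
  H <- Matrix::Matrix(0, ntot, ntot, sparse = TRUE)
  for (k in seq_len(f)) {
    term <- Matrix::Matrix(Matrix::drop0(methods::as(
      as.matrix(kinetic_parts[[k]]), "CsparseMatrix")), sparse = TRUE)
    if (k > 1)
      term <- Matrix::kronecker(Matrix::Diagonal(prod(sizes[1:(k - 1)])), term)
    if (k < f)
      term <- Matrix::kronecker(term, Matrix::Diagonal(prod(sizes[(k + 1):f])))
    H <- H + term
  }
  H <- H + Matrix::Diagonal(ntot, x = V_multi)
  attr(H, "dims") <- f
  H
}

#' Lowest eigenpairs of a symmetric matrix
#'
#' Dense path (LAPACK `eigen`) for small matrices, iterative sparse path
#' (implicitly restarted Lanczos via RSpectra) above a configurable size
#' threshold or on request.  Only the lower triangle is referenced on the
#' dense path, matching the convention that the lower-triangular portion of a
#' workspace matrix is authoritative.
#'
#' @param H Symmetric matrix (base matrix or Matrix sparse).
#' @param k Number of lowest eigenpairs requested (`k <= nrow(H)` on the
#'   dense path; strictly smaller on the iterative path).
#' @param method `"auto"` (dense up to `dense_limit`), `"dense"` or
#'   `"sparse_iterative"`.
#' @param dense_limit Size threshold for the automatic choice (default 2000).
#' @return List with `values` (ascending), `vectors` (unit-norm columns),
#'   `k`, `method`.
#' @export
solve_lowest <- function(H, k, method = c("auto", "dense", "sparse_iterative"),
                         dense_limit = 2000) {
  method <- match.arg(method)
  n <- nrow(H)
  if (k > n) stop("k must not exceed the matrix size")
  if (method == "auto")
    method <- if (n <= dense_limit) "dense" else "sparse_iterative"
  if (method == "sparse_iterative" && k >= n)
    stop("the iterative path needs k strictly smaller than the matrix size")
  if (method == "dense") {
    Hd <- symmetrize_lower(as.matrix(H))
    e <- eigen(Hd, symmetric = TRUE)
    ord <- n:1
    vals <- e$values[ord][seq_len(k)]
    vecs <- e$vectors[, ord, drop = FALSE][, seq_len(k), drop = FALSE]
  } else {
    Hs <- methods::as(Matrix::forceSymmetric(
      methods::as(H, "CsparseMatrix"), uplo = "L"), "generalMatrix")
    e <- RSpectra::eigs_sym(Hs, k = k, which = "SA",
                            opts = list(maxitr = 10000, tol = 1e-12))
    if (length(e$values) < k)
      stop("sparse iterative eigensolver did not converge: got ",
           length(e$values), " of ", k, " eigenpairs (niter = ",
           e$niter, ")")
    ord <- order(e$values)
    vals <- e$values[ord]
    vecs <- e$vectors[, ord, drop = FALSE]
  }
  vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), "/")
  list(values = vals, vectors = vecs, k = k, method = method)
}

# reflect the lower triangle onto the upper one
symmetrize_lower <- function(M) {
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  M
}

#' Count (near-)nonzero matrix elements
#'
#' @param H Matrix (dense or sparse).
#' @param tol Magnitude threshold; elements with `|h| > tol` count as
#'   nonzero (default 1e-12).
#' @return List with `count` and `fraction` (`count / n^2`).
#' @export
count_nonzeros <- function(H, tol = 1e-12) {
  n <- nrow(H)
  cnt <- if (inherits(H, "sparseMatrix")) {
    # symmetric sparse classes store one triangle only; expand first
    sum(abs(methods::as(methods::as(H, "generalMatrix"),
                        "CsparseMatrix")@x) > tol)
  } else {
    sum(abs(H) > tol)
  }
  list(count = as.numeric(cnt), fraction = as.numeric(cnt) / (as.numeric(n)^2))
}

#' Export a sparse matrix in MatrixMarket coordinate format
#'
#' @param H Matrix to export (coerced to sparse).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_market <- function(H, path) {
  Matrix::writeMM(methods::as(Matrix::Matrix(H, sparse = TRUE),
                              "generalMatrix"), path)
  invisible(path)
}
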