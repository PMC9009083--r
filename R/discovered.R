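#' Discovered solver algorithms
#'
#' Search-free access to the registry of discovered (program-synthesized)
#' solver rules.  These matrices approximate an effective Hamiltonian only
#' through their *eigenvectors*: their eigenvalues are generally not
#' energies, so energies must be computed as expectation values of the
#' predicted wave functions ([expectation_energy()]).  See
#' `R/discovered-registry.R` for the per-label provenance notes; the shipped
#' rules are synthetic reconstructions of unavailable published forms.
#'
#' @param label One of `"C20Tri_E1_A"`, `"C20Full_E1_A"`, `"C25Full_E1_A"`,
#'   `"C15Full_E1_A"`.
#' @return A `discovered_algorithm` object.
#' @export
discovered_algorithm <- function(label) {
  reg <- discovered_registry()
  if (!label %in% names(reg))
    stop("unregistered discovered algorithm '", label, "'; available: ",
         paste(names(reg), collapse = ", "))
  structure(reg[[label]], class = "discovered_algorithm")
}

#' @export
print.discovered_algorithm <- function(x, ...) {
  cat(sprintf("<discovered_algorithm %s> structure: %s (%s)\n",
              x$label, x$structure, x$provenance))
  invisible(x)
}

#' Build the workspace matrix of a discovered algorithm
#'
#' @param alg A [discovered_algorithm()] (or its label).
#' @param V Potential on the grid.
#' @param grid A [make_uniform_grid()] grid.
#' @param m Mass (default 1, the published regime).
#' @return Dense `n_g x n_g` matrix; exactly tridiagonal for tridiagonal
#'   rules.
#' @export
build_matrix <- function(alg, V, grid, m = 1) {
  if (is.character(alg)) alg <- discovered_algorithm(alg)
  check_V_grid(V, grid)
  M <- alg$elements(V, grid, m)
  attr(M, "source") <- alg$label
  M
}

#' Solve a potential with a discovered algorithm
#'
#' Computes the `n_e` lowest eigenvectors of the discovered rule's workspace
#' matrix (assembled by Kronecker sum across dimensions when more than one
#' grid is supplied, with the full multidimensional potential on the
#' diagonal) and evaluates the per-state energies as expectation values.
#' Requesting matrix eigenvalues as energies is refused: discovered rules
#' reproduce eigenvectors of the Hamiltonian, not its spectrum.
#'
#' For multidimensional problems the expectation energies are currently
#' evaluated only for `f = 1`; higher dimensions return eigenvectors with
#' `energies = NULL` (grid quadrature of multidimensional kinetic terms is
#' out of scope).
#'
#' @param alg A [discovered_algorithm()] or label.
#' @param pes A `psdvr_pes`, or a numeric vector of potential values.
#' @param grid A grid or list of grids (one per dimension).
#' @param n_e Number of states.
#' @param m Mass.
#' @param energy_mode Only `"expectation"` is allowed.
#' @return List with `vectors`, `energies` (expectation values; 1-D only),
#'   `values` (raw matrix eigenvalues, NOT energies), `method`.
#' @export
solve_discovered <- function(alg, pes, grid, n_e = 3, m = 1,
                             energy_mode = c("expectation", "eigenvalue")) {
  energy_mode <- match.arg(energy_mode)
  if (energy_mode == "eigenvalue")
    stop("matrix eigenvalues of discovered codes are not energies ",
         "(composite-cost failure mode); use energy_mode = 'expectation'")
  if (is.character(alg)) alg <- discovered_algorithm(alg)
  grids <- if (is_grid(grid)) list(grid) else grid
  f <- length(grids)
  if (f == 1L) {
    g <- grids[[1]]
    V <- if (is.numeric(pes)) pes else evaluate_pes(pes, g$points)
    M <- build_matrix(alg, V, g, m)
    sol <- solve_lowest(M, n_e)
    energies <- vapply(seq_len(n_e), function(k)
      expectation_energy(sol$vectors[, k], V, g, m), numeric(1))
    list(vectors = sol$vectors, energies = energies, values = sol$values,
         method = sol$method)
  } else {
    V_multi <- if (is.numeric(pes)) pes else evaluate_pes_on_grid(pes, grids)
    kin <- lapply(grids, function(g)
      build_matrix(alg, numeric(g$n_g), g, m))
    H <- assemble_direct_product(kin, V_multi)
    sol <- solve_lowest(H, n_e)
    list(vectors = sol$vectors, energies = NULL, values = sol$values,
         method = sol$method)
  }
}

#' Solve a potential with a reference DVR
#'
#' Convenience front end mirroring [solve_discovered()] for the true
#' Hamiltonian constructors, where matrix eigenvalues *are* energies.
#'
#' @param solver `"cmdvr"` or `"fd"`.
#' @inheritParams solve_discovered
#' @return List with `vectors`, `energies` (= eigenvalues), `method`.
#' @export
solve_dvr <- function(solver = c("cmdvr", "fd"), pes, grid, n_e = 3, m = 1) {
  solver <- match.arg(solver)
  builder <- if (solver == "cmdvr") cmdvr_hamiltonian_1d else fd_hamiltonian_1d
  grids <- if (is_grid(grid)) list(grid) else grid
  if (length(grids) == 1L) {
    g <- grids[[1]]
    V <- if (is.numeric(pes)) pes else evaluate_pes(pes, g$points)
    sol <- solve_lowest(builder(V, g, m), n_e)
  } else {
    V_multi <- if (is.numeric(pes)) pes else evaluate_pes_on_grid(pes, grids)
    kin <- lapply(grids, function(g) builder(numeric(g$n_g), g, m))
    H <- assemble_direct_product(kin, V_multi)
    sol <- solve_lowest(H, n_e)
  }
  list(vectors = sol$vectors, energies = sol$values, method = sol$method)
}
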