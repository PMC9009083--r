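#' Generate a set of target input/output examples
#'
#' Each target problem pairs a random bound-polynomial potential tabulated on
#' a coarse uniform grid (the solver input) with oracle wave functions and
#' energies from a converged Colbert-Miller calculation on a fine grid (the
#' expected output).  In `grid_mode = "variable"` the coarse grid size is an
#' odd integer drawn uniformly from `ng_range` - training across grid sizes
#' is what makes discovered codes transferable; `"fixed"` uses `ng_fixed`
#' for every problem.
#'
#' @param M Number of target problems (default 20).
#' @param n_e Number of target states per problem (default 3).
#' @param grid_mode `"variable"` or `"fixed"`.
#' @param ng_range Inclusive range of odd coarse grid sizes (default
#'   `c(15, 91)`).
#' @param ng_fixed Grid size used in `"fixed"` mode (default 51).
#' @param oracle_n_g Fine oracle grid size (default 151).
#' @param range Coordinate range (default `c(-5, 5)`).
#' @param m Mass (default 1).
#' @param degree Polynomial degree for the random potentials.
#' @return A `target_set`: list of `target_problem`s, each with fields
#'   `grid`, `V`, `m`, `pes` and `targets` (oracle `grid`, unit-norm `psi`
#'   columns, ascending `energies`).  Potentials follow the energy-zero
#'   convention: the fine-grid minimum of each accepted well is shifted to
#'   zero (recorded in `pes$shift`), so oracle energies are positive and
#'   fractional energy errors are well defined.
#' @export
generate_target_set <- function(M = 20, n_e = 3,
                                grid_mode = c("variable", "fixed"),
                                ng_range = c(15, 91), ng_fixed = 51,
                                oracle_n_g = 151, range = c(-5, 5),
                                m = 1, degree = 4) {
  grid_mode <- match.arg(grid_mode)
  stopifnot(M >= 1)
  oracle_grid <- make_uniform_grid(range[1], range[2], oracle_n_g)
  odd_sizes <- seq(ng_range[1] + (ng_range[1] %% 2 == 0),
                   ng_range[2], by = 2)
  problems <- vector("list", M)
  for (j in seq_len(M)) {
    pes <- sample_bound_polynomial(degree = degree, range = range)
    # energy-zero convention: measure energies from the well minimum (the
    # fine-grid minimum of V).  Vibrational energies are then strictly
    # positive and bounded away from zero by the zero-point energy, which
    # keeps fractional energy errors well defined across ensembles.
    pes$shift <- min(evaluate_pes(pes, oracle_grid$points))
    n_g <- if (grid_mode == "variable") sample(odd_sizes, 1) else ng_fixed
    grid <- make_uniform_grid(range[1], range[2], n_g)
    V <- evaluate_pes(pes, grid$points)
    V_oracle <- evaluate_pes(pes, oracle_grid$points)
    sol <- solve_lowest(cmdvr_hamiltonian_1d(V_oracle, oracle_grid, m), n_e,
                        method = "dense")
    problems[[j]] <- structure(
      list(grid = grid, V = V, m = m, pes = pes,
           targets = list(grid = oracle_grid, psi = sol$vectors,
                          energies = sol$values)),
      class = "target_problem")
  }
  structure(list(problems = problems, n_e = n_e, m = m,
                 grid_mode = grid_mode, oracle_n_g = oracle_n_g),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  ngs <- vapply(x$problems, function(p) p$grid$n_g, integer(1))
  cat(sprintf("<target_set> M=%d problems, n_e=%d, n_g in [%d, %d], oracle n_g=%d\n",
              length(x$problems), x$n_e, min(ngs), max(ngs), x$oracle_n_g))
  invisible(x)
}

#' Execute a code on every problem of a target set
#'
#' @param code A [ps_code()].
#' @param target_set A [generate_target_set()] result.
#' @param n_e States per problem.
#' @param library Function library.
#' @return List of per-problem execution results (see [execute_code()]).
#' @export
execute_on_set <- function(code, target_set, n_e = target_set$n_e,
                           library = default_library()) {
  lapply(target_set$problems, execute_code, code = code, n_e = n_e,
         library = library)
}
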