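#' Run a program-synthesis training campaign
#'
#' Performs `n_runs` independent annealing optimizations, each against a
#' freshly generated target set, and summarises success against the
#' training-cost threshold (default 2e-2, the "good algorithm" criterion).
#' For the composite cost the success rule and traces use the energy
#' component, which is the quantity comparable across methods.
#'
#' @param method `"E1"` (expectation-energy cost) or `"E2"` (composite).
#' @param N Code size.
#' @param n_runs Number of independent optimizations (the full published
#'   protocol uses 100; that takes hours - scale down for interactive use).
#' @param structure `"full"` or `"tridiagonal"`.
#' @param M,n_e,T_init,N_iter Protocol parameters (defaults 20, 3, 5e3, 5e3).
#' @param threshold Success threshold on the (energy-component) cost.
#' @param seed Integer seed; run `r` uses `seed + r` so campaigns are
#'   replayable run by run.
#' @param library Function library.
#' @return A `ps_campaign`: per-run records (`final_energy_cost`,
#'   `best_cost`, `best_code`, `trace`), `successes`, `success_rate`.
#' @export
run_campaign <- function(method = c("E1", "E2"), N = 20, n_runs = 5,
                         structure = c("full", "tridiagonal"), M = 20,
                         n_e = 3, T_init = 5e3, N_iter = 5e3,
                         threshold = 2e-2, seed = 1,
                         library = default_library()) {
  method <- match.arg(method)
  structure <- match.arg(structure)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    ts <- generate_target_set(M = M, n_e = n_e)
    run <- anneal(ts, N = N, cost = if (method == "E1") "e1" else "e2",
                  n_e = n_e, T_init = T_init, N_iter = N_iter,
                  tridiagonal = (structure == "tridiagonal"),
                  library = library)
    final_energy <- if (method == "E1") run$best_cost else
      run$best_report$components[["energy"]]
    runs[[r]] <- list(seed = seed + r, best_code = run$best_code,
                      best_cost = run$best_cost,
                      final_energy_cost = final_energy,
                      trace = run$best_trace,
                      energy_trace = run$energy_trace)
  }
  succ <- vapply(runs, function(r) r$final_energy_cost <= threshold,
                 logical(1))
  structure(list(method = method, N = N, structure = structure,
                 runs = runs, successes = sum(succ),
                 success_rate = mean(succ), threshold = threshold,
                 seed = seed, library_version = library$version),
            class = "ps_campaign")
}

#' @export
print.ps_campaign <- function(x, ...) {
  cat(sprintf("<ps_campaign %s N=%d %s> %d/%d runs below %g\n",
              x$method, x$N, x$structure, x$successes, length(x$runs),
              x$threshold))
  invisible(x)
}

# wrap a solver name/label into a prediction function for a target problem
solver_predictor <- function(solver) {
  if (is.function(solver)) return(solver)
  if (solver %in% c("cmdvr", "fd")) {
    builder <- if (solver == "cmdvr") cmdvr_hamiltonian_1d else
      fd_hamiltonian_1d
    function(problem, n_e) {
      sol <- solve_lowest(builder(problem$V, problem$grid, problem$m), n_e)
      list(failed = FALSE, values = sol$values, vectors = sol$vectors)
    }
  } else {
    alg <- discovered_algorithm(solver)
    function(problem, n_e) {
      sol <- solve_lowest(build_matrix(alg, problem$V, problem$grid,
                                       problem$m), n_e)
      list(failed = FALSE, values = sol$values, vectors = sol$vectors)
    }
  }
}

#' Grid-size convergence sweep
#'
#' For each solver and each grid size, generates `n_test` random
#' bound-polynomial potentials at that fixed grid size and reports the RMS
#' fractional energy error against the converged fine-grid oracle.  True
#' Hamiltonian solvers (`"cmdvr"`, `"fd"`) are scored on their matrix
#' eigenvalues; discovered codes on expectation-value energies (their
#' eigenvalues are not energies).
#'
#' @param solvers Character vector of solver names: `"cmdvr"`, `"fd"`, or a
#'   registry label such as `"C20Tri_E1_A"`.
#' @param ng_list Grid sizes to sweep.
#' @param n_test Random potentials per grid size (published protocol: 500).
#' @param n_e States per problem.
#' @param seed Integer seed.
#' @return An `evaluation_report` data frame: solver, n_g, n_test, E_f.
#' @export
convergence_sweep <- function(solvers = c("cmdvr", "fd", "C20Tri_E1_A"),
                              ng_list = c(21, 41, 61, 81), n_test = 50,
                              n_e = 3, seed = 1) {
  rows <- list()
  if (n_test > 0) {
    # one PES ensemble per sweep: every solver and grid size sees the same
    # potentials, so error-vs-n_g curves are comparable point by point
    set.seed(seed)
    ts_master <- generate_target_set(M = n_test, n_e = n_e,
                                     grid_mode = "fixed", ng_fixed = 3)
    for (ng in ng_list) {
      ts <- ts_master
      for (j in seq_along(ts$problems)) {
        p <- ts$problems[[j]]
        p$grid <- make_uniform_grid(p$targets$grid$points[1],
                                    p$targets$grid$points[p$targets$grid$n_g],
                                    ng)
        p$V <- evaluate_pes(p$pes, p$grid$points)
        ts$problems[[j]] <- p
      }
      for (s in solvers) {
        pred <- solver_predictor(s)
        route <- if (s %in% c("cmdvr", "fd")) "eigenvalue" else "expectation"
        fr <- fractional_errors(lapply(ts$problems, pred, n_e = n_e), ts,
                                n_e, energy_from = route)
        rows[[length(rows) + 1L]] <- data.frame(
          solver = s, n_g = ng, n_test = n_test,
          E_f = sqrt(mean(fr$delta^2)), energy_route = route)
      }
    }
  }
  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(solver = character(0), n_g = integer(0),
               n_test = integer(0), E_f = numeric(0),
               energy_route = character(0))
  attr(rep, "seed") <- seed
  class(rep) <- c("evaluation_report", class(rep))
  rep
}

#' Sparsity report for multidimensional assemblies
#'
#' Fractions of structurally nonzero elements (|h| > tol) in direct-product
#' working matrices built from tridiagonal 1-D rules versus the dense
#' sinc-DVR kinetic coupling, with the CM-DVR / tridiagonal count ratio.
#' Closed forms: 2-D tridiagonal `5n^2 - 4n`; 2-D CM-DVR `2n^3 - n^2`; 3-D
#' tridiagonal `7n^3 - 6n^2`; 3-D CM-DVR `n^3 (3n - 2)`.
#'
#' @param dims 2 or 3.
#' @param ng_list Per-dimension grid sizes to tabulate.
#' @param tol Nonzero threshold (default 1e-12).
#' @return Data frame: n_g, nnz and fraction per builder, ratio, and the
#'   closed-form counts for cross-checking.
#' @export
sparsity_report <- function(dims = 2, ng_list = c(5, 7, 9, 11), tol = 1e-12) {
  stopifnot(dims %in% c(2, 3))
  rows <- lapply(ng_list, function(n) {
    g <- make_uniform_grid(-5, 5, n)
    V0 <- numeric(n)
    ktri <- build_matrix("C20Tri_E1_A", V0, g)
    kcm <- cmdvr_hamiltonian_1d(V0, g)
    Vm <- numeric(n^dims)
    Htri <- assemble_direct_product(rep(list(ktri), dims), Vm)
    Hcm <- assemble_direct_product(rep(list(kcm), dims), Vm)
    # zero diagonal potential leaves structural diagonals nonzero via the
    # kinetic parts, so counts are structural
    ctri <- count_nonzeros(Htri, tol)
    ccm <- count_nonzeros(Hcm, tol)
    closed_tri <- if (dims == 2) 5 * n^2 - 4 * n else 7 * n^3 - 6 * n^2
    closed_cm <- if (dims == 2) 2 * n^3 - n^2 else n^3 * (3 * n - 2)
    data.frame(n_g = n, nnz_tridiagonal = ctri$count,
               nnz_cmdvr = ccm$count,
               fraction_tridiagonal = ctri$fraction,
               fraction_cmdvr = ccm$fraction,
               ratio_cm_over_tri = ccm$count / ctri$count,
               closed_form_tridiagonal = closed_tri,
               closed_form_cmdvr = closed_cm)
  })
  do.call(rbind, rows)
}

#' Relative eigensolution timing (diagnostic only)
#'
#' Wall-clock ratio of sparse eigensolution time for the CM-DVR assembly
#' versus a tridiagonal-rule assembly.  Hardware-dependent; reported for
#' orientation only and deliberately excluded from any acceptance surface.
#'
#' @inheritParams sparsity_report
#' @param n_e Eigenpairs to compute.
#' @return Data frame with times and their ratio.
#' @export
timing_report <- function(dims = 2, ng_list = c(15, 21), n_e = 6) {
  rows <- lapply(ng_list, function(n) {
    g <- make_uniform_grid(-5, 5, n)
    pes <- model_pes(if (dims == 3) "henon_heiles_3d" else "double_well_2d")
    Vm <- evaluate_pes_on_grid(pes, rep(list(g), dims))
    ktri <- build_matrix("C20Tri_E1_A", numeric(n), g)
    kcm <- cmdvr_hamiltonian_1d(numeric(n), g)
    Htri <- assemble_direct_product(rep(list(ktri), dims), Vm)
    Hcm <- assemble_direct_product(rep(list(kcm), dims), Vm)
    t_tri <- system.time(solve_lowest(Htri, n_e,
                                      method = "sparse_iterative"))[["elapsed"]]
    t_cm <- system.time(solve_lowest(Hcm, n_e,
                                     method = "sparse_iterative"))[["elapsed"]]
    data.frame(n_g = n, t_cmdvr = t_cm, t_tridiagonal = t_tri,
               acceleration = t_cm / max(t_tri, .Machine$double.eps))
  })
  do.call(rbind, rows)
}
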