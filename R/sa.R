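#' Metropolis acceptance rule
#'
#' Accept a proposed cost `F_new` against `F_old` at effective temperature
#' `T` with probability `min(1, exp(-(F_new - F_old)/T))`.  At `T = 0` the
#' rule degenerates to accepting iff `F_new <= F_old`.
#'
#' @param F_new,F_old Proposed and current cost.
#' @param T Effective temperature, `>= 0`.
#' @return Logical.
#' @export
metropolis_accept <- function(F_new, F_old, T) {
  stopifnot(T >= 0)
  if (F_new <= F_old) return(TRUE)
  if (T == 0 || !is.finite(F_new)) return(FALSE)
  stats::runif(1) < exp(-(F_new - F_old) / T)
}

#' Linear cooling schedule
#'
#' `T_j = T_init * (1 - j/N_iter)`: starts at `T_init`, reaches exactly 0 at
#' the final iteration.
#'
#' @param T_init Initial effective temperature.
#' @param N_iter Total number of iterations.
#' @param j Iteration index, `0 <= j <= N_iter`.
#' @export
linear_schedule <- function(T_init, N_iter, j) {
  stopifnot(all(j >= 0), all(j <= N_iter))
  T_init * (1 - j / N_iter)
}

#' Simulated-annealing search over code sequences
#'
#' Minimises a cost function over linear codes of size `N`: starting from a
#' uniformly random valid code, each iteration mutates 1-3 instructions,
#' executes the candidate on every problem of the target set, scores it, and
#' accepts or rejects by the Metropolis rule under the linear cooling
#' schedule.  Failed executions score `+Inf` (worst case) so the chain
#' simply walks around invalid genotypes.  The best code seen is tracked
#' separately from the current one.
#'
#' @param target_set A [generate_target_set()] result.
#' @param N Code size.
#' @param cost One of `"e1"`, `"e2"`, `"wavefunction"`, or a function
#'   `(predictions, target_set, n_e) -> cost_report`.
#' @param n_e States scored per problem.
#' @param T_init Initial temperature (default 5e3).
#' @param N_iter Attempted code updates (default 5e3).
#' @param tridiagonal Impose tridiagonal output structure on every candidate.
#' @param library Function library.
#' @param patience Abort if this many consecutive initial candidates all
#'   fail (default 1000).
#' @param trace_components Record the energy component of the cost per
#'   iteration as well (used when `cost = "e2"` so traces are comparable to
#'   E1 runs).
#' @return A `sa_run` record: `best_code`, `best_cost`, `trace`
#'   (length-`N_iter` vector of current cost), `best_trace`,
#'   `energy_trace`, `accepted` count.
#' @export
anneal <- function(target_set, N = 20, cost = "e1", n_e = target_set$n_e,
                   T_init = 5e3, N_iter = 5e3, tridiagonal = FALSE,
                   library = default_library(), patience = 1000,
                   trace_components = TRUE) {
  cost_fn <- if (is.function(cost)) cost else switch(
    cost,
    e1 = e1_cost,
    e2 = e2_cost,
    wavefunction = wavefunction_cost,
    stop("unknown cost '", cost, "'"))

  score <- function(code) {
    preds <- execute_on_set(code, target_set, n_e, library)
    cost_fn(preds, target_set, n_e)
  }

  current <- random_code(N, library, tridiagonal)
  rep_cur <- score(current)
  tries <- 0
  while (!is.finite(rep_cur$F)) {
    tries <- tries + 1
    if (tries > patience)
      stop("annealing aborted: ", patience,
           " consecutive initial candidates failed execution")
    current <- random_code(N, library, tridiagonal)
    rep_cur <- score(current)
  }
  best <- current; rep_best <- rep_cur
  trace <- numeric(N_iter); best_trace <- numeric(N_iter)
  energy_trace <- numeric(N_iter)
  accepted <- 0L
  for (j in seq_len(N_iter)) {
    Tj <- linear_schedule(T_init, N_iter, j)
    cand <- mutate_code(current, library)
    rep_cand <- score(cand)
    if (metropolis_accept(rep_cand$F, rep_cur$F, Tj)) {
      current <- cand; rep_cur <- rep_cand
      accepted <- accepted + 1L
      if (rep_cur$F < rep_best$F) { best <- current; rep_best <- rep_cur }
    }
    trace[j] <- rep_cur$F
    best_trace[j] <- rep_best$F
    energy_trace[j] <- if (trace_components)
      rep_cur$components[["energy"]] else NA_real_
  }
  structure(list(best_code = best, best_cost = rep_best$F,
                 best_report = rep_best, trace = trace,
                 best_trace = best_trace, energy_trace = energy_trace,
                 accepted = accepted, N_iter = N_iter, T_init = T_init),
            class = "sa_run")
}

#' @export
print.sa_run <- function(x, ...) {
  cat(sprintf("<sa_run> %d iterations, %d accepted, best cost %g\n",
              x$N_iter, x$accepted, x$best_cost))
  invisible(x)
}
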