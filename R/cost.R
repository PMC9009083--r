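#' Sign alignment of a predicted eigenvector
#'
#' Both `+psi` and `-psi` solve the eigenproblem, so every comparison first
#' chooses the overall sign `S` maximising the inner product
#' `<psi, S w>`; exact ties (orthogonal vectors) resolve to `S = +1`.
#'
#' @param w Predicted vector.
#' @param psi Reference vector of equal length.
#' @return List with `S` (+1 or -1) and `aligned` (`S * w`).
#' @export
align_sign <- function(w, psi) {
  stopifnot(length(w) == length(psi))
  S <- if (sum(w * psi) < 0) -1 else 1
  list(S = S, aligned = S * w)
}

#' Nearest-point resampling of a fine-grid target onto a coarse grid
#'
#' For each coarse grid point the value at the *closest* fine grid point is
#' selected; distance ties resolve to the lower fine index.  Used to compare
#' solver output on a coarse grid against oracle wave functions tabulated on
#' the fine oracle grid.
#'
#' @param coarse_grid,fine_grid Grids spanning the same range.
#' @return Integer index vector of length `coarse_grid$n_g` into the fine
#'   grid.
#' @export
nearest_index_map <- function(coarse_grid, fine_grid) {
  vapply(coarse_grid$points,
         function(z) which.min(abs(fine_grid$points - z)), integer(1))
}

#' @rdname nearest_index_map
#' @param values Fine-grid values to resample.
#' @export
resample_to_target <- function(values, coarse_grid, fine_grid) {
  values[nearest_index_map(coarse_grid, fine_grid)]
}

# resampled, unit-normalised oracle state k for problem p
target_state_on_coarse <- function(problem, k) {
  idx <- nearest_index_map(problem$grid, problem$targets$grid)
  v <- problem$targets$psi[idx, k]
  v / sqrt(sum(v^2))
}

worst_cost <- function() {
  structure(list(F = Inf, per_problem = numeric(0), signs = list(),
                 components = c(wavefunction = Inf, energy = Inf)),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("<cost_report> F = %g", x$F))
  if (all(is.finite(x$components)))
    cat(sprintf("  (wavefunction %g, energy %g)",
                x$components[["wavefunction"]], x$components[["energy"]]))
  cat("\n")
  invisible(x)
}

#' Wave-function cost
#'
#' Mean over problems and states of the root-mean-square element-wise
#' deviation between the (nearest-point resampled, unit-normalised,
#' sign-aligned) oracle wave function and the predicted eigenvector.  Zero
#' iff every state matches exactly up to sign.
#'
#' @param predictions [execute_on_set()] output.
#' @param target_set The target set the predictions refer to.
#' @param n_e Number of states scored per problem.
#' @return A `cost_report` with fields `F`, `per_problem`, `signs`,
#'   `components`.
#' @export
wavefunction_cost <- function(predictions, target_set, n_e = target_set$n_e) {
  per <- numeric(length(target_set$problems))
  signs <- vector("list", length(per))
  for (j in seq_along(target_set$problems)) {
    pr <- target_set$problems[[j]]
    pd <- predictions[[j]]
    if (is.null(pd) || pd$failed || ncol(pd$vectors) < n_e)
      return(worst_cost())
    dev <- numeric(n_e); sg <- integer(n_e)
    for (k in seq_len(n_e)) {
      psi <- target_state_on_coarse(pr, k)
      al <- align_sign(pd$vectors[, k], psi)
      sg[k] <- al$S
      dev[k] <- sqrt(mean((al$aligned - psi)^2))
    }
    per[j] <- mean(dev)
    signs[[j]] <- sg
  }
  FF <- mean(per)
  structure(list(F = FF, per_problem = per, signs = signs,
                 components = c(wavefunction = FF, energy = 0)),
            class = "cost_report")
}

# RMS fractional error helper; excludes |reference| < 1e-10 with a warning
rms_fractional <- function(E, E_ref) {
  keep <- abs(E_ref) >= 1e-10
  if (!all(keep))
    warning(sum(!keep), " state(s) with |reference energy| < 1e-10 excluded ",
            "from the fractional error")
  if (!any(keep)) return(NaN)
  sqrt(mean(((E[keep] - E_ref[keep]) / E_ref[keep])^2))
}

#' Energy-expectation cost (method E1)
#'
#' Root-mean-square fractional error, over all problems and states, between
#' the expectation-value energies of the predicted eigenvectors and the
#' oracle energies.  Because the energies are computed *from* the predicted
#' wave functions, a small value requires both eigenvectors and energies to
#' be accurate.
#'
#' @inheritParams wavefunction_cost
#' @param beta_kernel,quadrature_refine Passed to [expectation_energy()].
#' @return A `cost_report`.
#' @export
e1_cost <- function(predictions, target_set, n_e = target_set$n_e,
                    beta_kernel = 0.5, quadrature_refine = 4L) {
  fr <- fractional_errors(predictions, target_set, n_e,
                          beta_kernel = beta_kernel,
                          quadrature_refine = quadrature_refine,
                          energy_from = "expectation")
  if (is.null(fr)) return(worst_cost())
  FF <- sqrt(mean(fr$delta^2))
  structure(list(F = FF, per_problem = fr$per_problem, signs = list(),
                 components = c(wavefunction = 0, energy = FF)),
            class = "cost_report")
}

#' Composite cost (method E2)
#'
#' Sum of the wave-function cost and the RMS fractional error of the
#' workspace-matrix *eigenvalues* against the oracle energies.  Both
#' components are reported separately, since the energy part alone is the
#' quantity comparable to method E1.
#'
#' @inheritParams wavefunction_cost
#' @return A `cost_report` whose `components` sum to `F`.
#' @export
e2_cost <- function(predictions, target_set, n_e = target_set$n_e) {
  wf <- wavefunction_cost(predictions, target_set, n_e)
  if (!is.finite(wf$F)) return(worst_cost())
  fr <- fractional_errors(predictions, target_set, n_e,
                          energy_from = "eigenvalue")
  if (is.null(fr)) return(worst_cost())
  en <- sqrt(mean(fr$delta^2))
  structure(list(F = wf$F + en, per_problem = wf$per_problem,
                 signs = wf$signs,
                 components = c(wavefunction = wf$F, energy = en)),
            class = "cost_report")
}

#' Per-state fractional energy errors of predictions on a target set
#'
#' Returns `(E - E_oracle)/E_oracle` for every (problem, state), with `E`
#' either the expectation value of the predicted eigenvector (default; the
#' only meaningful route for discovered codes) or the raw matrix eigenvalue.
#'
#' @inheritParams e1_cost
#' @param energy_from `"expectation"` or `"eigenvalue"`.
#' @return `NULL` if any prediction failed, otherwise a list with `delta`
#'   (vector of fractional errors), `per_problem` (per-problem RMS), and
#'   `table` (data frame: problem, state, n_g, E, E_oracle, delta).
#' @export
fractional_errors <- function(predictions, target_set, n_e = target_set$n_e,
                              energy_from = c("expectation", "eigenvalue"),
                              beta_kernel = 0.5, quadrature_refine = 4L) {
  energy_from <- match.arg(energy_from)
  rows <- list()
  per <- numeric(length(target_set$problems))
  for (j in seq_along(target_set$problems)) {
    pr <- target_set$problems[[j]]
    pd <- predictions[[j]]
    if (is.null(pd) || pd$failed || ncol(pd$vectors) < n_e) return(NULL)
    E <- if (energy_from == "expectation") {
      vapply(seq_len(n_e), function(k)
        expectation_energy(pd$vectors[, k], pr$V, pr$grid, pr$m,
                           beta_kernel, quadrature_refine), numeric(1))
    } else {
      pd$values[seq_len(n_e)]
    }
    Et <- pr$targets$energies[seq_len(n_e)]
    keep <- abs(Et) >= 1e-10
    if (!all(keep))
      warning("problem ", j, ": ", sum(!keep),
              " state(s) with |oracle energy| < 1e-10 excluded")
    delta <- (E[keep] - Et[keep]) / Et[keep]
    per[j] <- sqrt(mean(delta^2))
    rows[[j]] <- data.frame(problem = j, state = which(keep),
                            n_g = pr$grid$n_g, E = E[keep],
                            E_oracle = Et[keep], delta = delta)
  }
  tab <- do.call(rbind, rows)
  list(delta = tab$delta, per_problem = per, table = tab)
}

#' Distribution of fractional energy errors for a solver
#'
#' Convenience wrapper evaluating a solver function on every problem of an
#' independent test set and returning the per-state fractional errors with
#' summary statistics.
#'
#' @param solver Function `(problem, n_e) -> list(values, vectors, failed)`,
#'   e.g. a wrapped discovered algorithm or DVR.
#' @param test_set A [generate_target_set()] result.
#' @param n_e States per problem.
#' @param energy_from `"expectation"` or `"eigenvalue"`.
#' @return List with `delta`, `rms`, `table`.
#' @export
fractional_error_distribution <- function(solver, test_set,
                                          n_e = test_set$n_e,
                                          energy_from = "expectation") {
  preds <- lapply(test_set$problems, solver, n_e = n_e)
  fr <- fractional_errors(preds, test_set, n_e, energy_from = energy_from)
  if (is.null(fr)) stop("solver failed on at least one test problem")
  list(delta = fr$delta, rms = sqrt(mean(fr$delta^2)), table = fr$table)
}
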