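#' Run configuration
#'
#' Bundles every protocol parameter with the published defaults: initial
#' temperature `T_init = 5e3`, `N_iter = 5e3` attempted code updates,
#' `M = 20` target examples, `n_e = 3` target states, coordinate range
#' `[-5, 5]`, odd training grid sizes in `[15, 91]`, oracle grid
#' `n_g = 151`, success threshold `2e-2`, adjacent-point kernel value
#' `beta_kernel = 0.5`.  Unknown keys are rejected by name.
#'
#' @param ... Overrides of the defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    T_init = 5e3, N_iter = 5e3, M = 20, n_e = 3,
    range = c(-5, 5), ng_min = 15, ng_max = 91, oracle_n_g = 151,
    threshold = 2e-2, beta_kernel = 0.5, quadrature_refine = 4,
    degree = 4, m = 1, seed = 1, out_dir = ".")
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)[1]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' Read a configuration file (YAML or JSON)
#'
#' @param path Configuration file; keys must be a subset of the
#'   [run_config()] keys.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configuration")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  run_config(as.list(vals))
}

#' Write the effective configuration next to a run's outputs
#'
#' Every campaign entry point freezes its effective configuration as JSON so
#' a run is replayable from (seed, config, library version).
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
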