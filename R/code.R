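#' Linear code sequences
#'
#' A solver candidate is encoded as `N` integers: position 1 indexes an input
#' option (workspace initialiser), positions `2..N-1` index internal options,
#' and position `N` indexes the output operation (fixed: eigendecomposition
#' of the workspace matrix).  The `tridiagonal` flag requests masking of all
#' matrix elements outside `|i - j| <= 1` immediately before the output
#' operation, which is how sparsity is imposed on discovered algorithms.
#'
#' @param instructions Integer vector of length `N >= 2`.
#' @param library A [default_library()] (used for validation and recorded by
#'   version).
#' @param tridiagonal Logical; mask the output matrix to its tridiagonal
#'   band before diagonalisation.
#' @return A `ps_code` object.
#' @export
ps_code <- function(instructions, library = default_library(),
                    tridiagonal = FALSE) {
  instructions <- as.integer(instructions)
  N <- length(instructions)
  if (N < 2) stop("a code needs at least an input and an output instruction")
  n_in <- length(library$input_options)
  n_int <- length(library$internal_options)
  n_out <- length(library$output_options)
  if (instructions[1] < 1 || instructions[1] > n_in)
    stop("input instruction out of range [1, ", n_in, "]")
  if (N > 2) {
    mid <- instructions[2:(N - 1)]
    if (any(mid < 1 | mid > n_int))
      stop("internal instruction out of range [1, ", n_int, "]")
  }
  if (instructions[N] < 1 || instructions[N] > n_out)
    stop("output instruction out of range [1, ", n_out, "]")
  structure(list(instructions = instructions, N = N,
                 library_version = library$version,
                 tridiagonal = isTRUE(tridiagonal)),
            class = "ps_code")
}

#' @export
print.ps_code <- function(x, ...) {
  cat(sprintf("<ps_code N=%d%s, library %s> [%s]\n", x$N,
              if (x$tridiagonal) ", tridiagonal" else "",
              x$library_version,
              paste(x$instructions, collapse = " ")))
  invisible(x)
}

#' Random valid code
#'
#' Uniformly random indices at every layer (the initialisation used by the
#' annealer).
#'
#' @inheritParams ps_code
#' @param N Code size.
#' @export
random_code <- function(N, library = default_library(), tridiagonal = FALSE) {
  ins <- c(sample.int(length(library$input_options), 1),
           if (N > 2) sample.int(length(library$internal_options), N - 2,
                                 replace = TRUE),
           sample.int(length(library$output_options), 1))
  ps_code(ins, library, tridiagonal)
}

apply_tridiagonal_mask <- function(M) {
  n <- nrow(M)
  idx <- seq_len(n)
  M[abs(outer(idx, idx, "-")) > 1] <- 0
  M
}

#' Execute a code on one target problem
#'
#' Initialises the workspace from the problem's potential and grid, applies
#' the internal instructions in sequence, optionally masks the matrix to its
#' tridiagonal band, and diagonalises (lower triangle authoritative) to
#' obtain the `n_e` lowest eigenpairs.  Eigenvectors are unit-normalised.
#' Any non-finite value arising during execution yields a failure signal
#' (`failed = TRUE`) rather than an error, so a stochastic search can simply
#' assign the candidate a worst-case cost.
#'
#' @param code A [ps_code()].
#' @param problem A `target_problem` (see [generate_target_set()]) or any
#'   list with fields `grid`, `V`, `m`.
#' @param n_e Number of eigenpairs to return.
#' @param library The function library (must match the code's version).
#' @return List with `failed`, and on success `values`, `vectors`
#'   (`n_g x n_e`, unit columns), `matrix` (the final workspace matrix).
#' @export
execute_code <- function(code, problem, n_e = 3, library = default_library()) {
  if (code$library_version != library$version)
    stop("code was written for library version '", code$library_version,
         "' but '", library$version, "' was supplied")
  grid <- problem$grid
  ws <- new_workspace(problem$V, grid$points, problem$m, grid$length, grid$dx)
  geo <- ws_geometry(ws)
  fail <- function() list(failed = TRUE)
  ws <- library$input_options[[code$instructions[1]]]$fn(ws, geo)
  if (code$N > 2) {
    for (j in 2:(code$N - 1)) {
      ws <- library$internal_options[[code$instructions[j]]]$fn(ws, geo)
      if (!all(is.finite(ws$M)) || !all(is.finite(ws$y))) return(fail())
    }
  }
  M <- ws$M
  if (code$tridiagonal) M <- apply_tridiagonal_mask(M)
  if (!all(is.finite(M))) return(fail())
  if (n_e > ws$n) return(fail())
  sol <- tryCatch(solve_lowest(M, n_e, method = "dense"),
                  error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol$values))) return(fail())
  list(failed = FALSE, values = sol$values, vectors = sol$vectors,
       matrix = symmetrize_lower(M))
}

#' Mutate a code sequence
#'
#' Draws `k` uniformly from 1..3, picks `k` distinct positions among the
#' `N - 1` mutable slots (the output layer is fixed) and replaces each with a
#' uniformly drawn valid alternative index for its layer.
#'
#' @inheritParams execute_code
#' @return A new `ps_code`.
#' @export
mutate_code <- function(code, library = default_library()) {
  N <- code$N
  k <- sample.int(3L, 1)
  k <- min(k, N - 1L)
  pos <- sample.int(N - 1L, k)
  ins <- code$instructions
  for (p in pos) {
    if (p == 1L) {
      ins[p] <- sample.int(length(library$input_options), 1)
    } else {
      ins[p] <- sample.int(length(library$internal_options), 1)
    }
  }
  ps_code(ins, library, code$tridiagonal)
}

#' Serialize / deserialize codes
#'
#' Codes round-trip through a small JSON document recording the integer
#' sequence, the tridiagonal flag and the library version; loading against a
#' different library version is refused.
#'
#' @param code A `ps_code`.
#' @param path File path.
#' @export
serialize_code <- function(code, path) {
  jsonlite::write_json(
    list(instructions = code$instructions,
         tridiagonal = code$tridiagonal,
         library_version = code$library_version),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname serialize_code
#' @param library Library the loaded code must match.
#' @export
deserialize_code <- function(path, library = default_library()) {
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$library_version, library$version))
    stop("code file was written for library version '", doc$library_version,
         "', but the supplied library is '", library$version,
         "'; register the matching library version before loading")
  ps_code(doc$instructions, library, isTRUE(doc$tridiagonal))
}
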