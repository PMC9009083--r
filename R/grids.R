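#' Uniform coordinate grid
#'
#' Construct a uniform 1-D coordinate grid with `n_g` points spanning
#' `[lower, upper]` (both endpoints included).  Grids are the coordinate
#' backbone of every solver in the package: the potential is tabulated on the
#' grid, wave functions are represented by their grid values, and the grid
#' spacing enters all kinetic-energy prefactors.
#'
#' @param lower,upper Real range of the grid; `upper > lower`.
#' @param n_g Number of grid points (>= 3; a tridiagonal structure is
#'   undefined below that).
#' @return An object of class `psdvr_grid` with fields `points`, `dx`,
#'   `length` (range `upper - lower`) and `n_g`.
#' @examples
#' g <- make_uniform_grid(-5, 5, 151)
#' g$dx            # 10/150
#' @export
make_uniform_grid <- function(lower, upper, n_g) {
  if (!is.numeric(lower) || !is.numeric(upper) || upper <= lower)
    stop("invalid grid range: need upper > lower")
  n_g <- as.integer(n_g)
  if (is.na(n_g) || n_g < 3L)
    stop("invalid grid: n_g must be an integer >= 3")
  pts <- seq(lower, upper, length.out = n_g)
  structure(
    list(points = pts, dx = (upper - lower) / (n_g - 1),
         length = upper - lower, n_g = n_g),
    class = "psdvr_grid")
}

#' @export
print.psdvr_grid <- function(x, ...) {
  cat(sprintf("<psdvr_grid> %d points on [%g, %g], dx = %g\n",
              x$n_g, x$points[1], x$points[x$n_g], x$dx))
  invisible(x)
}

is_grid <- function(x) inherits(x, "psdvr_grid")

#' Random bound-polynomial potential
#'
#' Draw a random bound polynomial potential on a coordinate grid range by
#' rejection sampling.  Coefficients act on the scaled coordinate
#' `u = 2x/L` (so that `u = +/-1` at the range endpoints) and are sampled
#' uniformly; a draw is accepted only when the potential at *both* endpoints
#' of the range exceeds `bound_threshold`, which guarantees a confining well
#' supporting bound states inside the box.
#'
#' The polynomial has no constant term: `V(x) = sum_k a_k u^k`, k = 1..degree.
#' Typical accepted wells are a few energy units deep with level spacings of
#' order one, i.e. the dimensionless analogue of a molecular vibrational
#' problem.
#'
#' @param degree Polynomial degree (default 4, quartic).
#' @param coeff_range Length-2 numeric, uniform sampling range of the
#'   coefficients (default `c(-5, 5)`).
#' @param bound_threshold Minimum value the candidate must attain at both
#'   range endpoints (default 5).
#' @param range Coordinate range the boundedness certificate refers to
#'   (default `c(-5, 5)`).
#' @param max_rejections Cap on redraws before failing (default 10000).
#' @return A `polynomial_pes` object with fields `coefficients` (ascending
#'   powers of `u`, no constant), `degree`, `range`, `rejections`.
#' @examples
#' set.seed(1)
#' pes <- sample_bound_polynomial()
#' evaluate_pes(pes, c(-5, 0, 5))
#' @export
sample_bound_polynomial <- function(degree = 4, coeff_range = c(-5, 5),
                                    bound_threshold = 5, range = c(-5, 5),
                                    max_rejections = 10000) {
  if (degree < 2) stop("degree must be >= 2 for a bound polynomial")
  rejections <- 0L
  repeat {
    a <- stats::runif(degree, coeff_range[1], coeff_range[2])
    pes <- structure(
      list(coefficients = a, degree = degree, range = range,
           rejections = rejections),
      class = c("polynomial_pes", "psdvr_pes"))
    vends <- evaluate_pes(pes, range)
    if (all(vends > bound_threshold)) return(pes)
    rejections <- rejections + 1L
    if (rejections > max_rejections)
      stop("bound-polynomial generation failed: rejection cap (",
           max_rejections, ") exceeded")
  }
}

#' Analytic model potentials
#'
#' Construct one of the built-in multidimensional model potentials used for
#' the 2-D/3-D demonstrations: the 2-D and 3-D Henon-Heiles potentials
#' (harmonic wells with the classic cubic mode-mode coupling, strength
#' `lambda`) and a 2-D double well along x bilinearly coupled to a harmonic
#' mode along y.  The double-well barrier height equals `eta`
#' (`V = x^4/(16 eta) - x^2/2 + y^2/2 + coupling * x * y`).
#'
#' The exact coefficients of the literature forms these families emulate were
#' not recoverable from the source used to build this package, so the shipped
#' parameterisations are synthetic reconstructions: canonical
#' `lambda = 0.111803` for Henon-Heiles, and `eta = 1.3544`,
#' `coupling = 0.3` for the double well.  All parameters may be overridden.
#'
#' @param family One of `"henon_heiles_2d"`, `"henon_heiles_3d"`,
#'   `"double_well_2d"`.
#' @param parameters Named list overriding the family defaults.
#' @return A `model_pes` object with fields `family`, `parameters`, `dims`.
#' @examples
#' dw <- model_pes("double_well_2d")
#' evaluate_pes(dw, cbind(0, 0))
#' @export
model_pes <- function(family = c("henon_heiles_2d", "henon_heiles_3d",
                                 "double_well_2d"),
                      parameters = list()) {
  family <- match.arg(family)
  defaults <- switch(family,
    henon_heiles_2d = list(lambda = 0.111803),
    henon_heiles_3d = list(lambda = 0.111803),
    double_well_2d  = list(eta = 1.3544, coupling = 0.3))
  unknown <- setdiff(names(parameters), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "))
  defaults[names(parameters)] <- parameters
  dims <- if (family == "henon_heiles_3d") 3L else 2L
  structure(list(family = family, parameters = defaults, dims = dims),
            class = c("model_pes", "psdvr_pes"))
}

#' Evaluate a potential at arbitrary coordinates
#'
#' @param pes A `polynomial_pes` or `model_pes`.
#' @param x For 1-D polynomials a numeric vector; for model potentials a
#'   matrix with one coordinate tuple per row (columns = dimensions).
#' @return Numeric vector of potential values.
#' @export
evaluate_pes <- function(pes, x) UseMethod("evaluate_pes")

#' @export
evaluate_pes.polynomial_pes <- function(pes, x) {
  u <- 2 * x / diff(pes$range)
  v <- numeric(length(x))
  up <- rep(1, length(x))
  for (k in seq_along(pes$coefficients)) {
    up <- up * u
    v <- v + pes$coefficients[k] * up
  }
  # energy-zero convention: a recorded offset (set by the target-generation
  # protocol to put the well minimum at zero) is subtracted uniformly
  v - (pes$shift %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
evaluate_pes.model_pes <- function(pes, x) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = pes$dims)
  if (ncol(x) != pes$dims)
    stop("coordinate tuples have ", ncol(x), " columns but '", pes$family,
         "' is ", pes$dims, "-dimensional")
  p <- pes$parameters
  switch(pes$family,
    henon_heiles_2d = {
      0.5 * (x[, 1]^2 + x[, 2]^2) +
        p$lambda * (x[, 1]^2 * x[, 2] - x[, 2]^3 / 3)
    },
    henon_heiles_3d = {
      0.5 * rowSums(x^2) +
        p$lambda * ((x[, 1]^2 * x[, 2] - x[, 2]^3 / 3) +
                    (x[, 2]^2 * x[, 3] - x[, 3]^3 / 3))
    },
    double_well_2d = {
      x[, 1]^4 / (16 * p$eta) - 0.5 * x[, 1]^2 + 0.5 * x[, 2]^2 +
        p$coupling * x[, 1] * x[, 2]
    })
}

#' Tabulate a potential on a (direct-product) grid
#'
#' For a single grid the result is a vector with one entry per grid point.
#' For a list of grids the potential is evaluated on the direct-product grid
#' in row-major order: the *first* coordinate varies slowest, the last
#' fastest.  This ordering is the package-wide convention and matches the
#' Kronecker ordering used by [assemble_direct_product()].
#'
#' @param pes A `polynomial_pes` or `model_pes`.
#' @param grid A `psdvr_grid`, or a list of them for multidimensional
#'   potentials.
#' @return Numeric vector of length `prod(n_g)`.
#' @export
evaluate_pes_on_grid <- function(pes, grid) {
  grids <- if (is_grid(grid)) list(grid) else grid
  stopifnot(all(vapply(grids, is_grid, logical(1))))
  f <- length(grids)
  pdim <- if (inherits(pes, "model_pes")) pes$dims else 1L
  if (pdim != f)
    stop("potential is ", pdim, "-dimensional but ", f, " grid(s) supplied")
  if (f == 1L) return(evaluate_pes(pes, grids[[1]]$points))
  coords <- expand.grid(rev(lapply(grids, function(g) g$points)),
                        KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first factor fastest; reverse to make the first
  # coordinate slowest (row-major)
  coords <- as.matrix(coords[, rev(seq_len(f)), drop = FALSE])
  colnames(coords) <- NULL
  evaluate_pes(pes, coords)
}

#' Read a potential specification or tabulated potential from file
#'
#' Two plain-text formats are supported: a JSON specification with either a
#' `family`/`parameters` pair (model potential) or a `coefficients` array
#' (bound polynomial in the scaled coordinate), and a whitespace/comma
#' separated two-column table `x V` which is interpolated linearly onto the
#' requested grid when solved.
#'
#' @param path File path.
#' @return A `psdvr_pes` object (`tabulated_pes` for two-column input).
#' @export
read_pes_file <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*\\{", first)) {
    spec <- jsonlite::fromJSON(path)
    if (!is.null(spec$family))
      return(model_pes(spec$family, as.list(spec$parameters)))
    if (is.null(spec$coefficients))
      stop("PES JSON must contain 'family' or 'coefficients'")
    rng <- if (is.null(spec$range)) c(-5, 5) else as.numeric(spec$range)
    return(structure(
      list(coefficients = as.numeric(spec$coefficients),
           degree = length(spec$coefficients), range = rng, rejections = NA),
      class = c("polynomial_pes", "psdvr_pes")))
  }
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#")
  if (ncol(tab) == 1L)
    tab <- utils::read.table(path, header = FALSE, sep = ",",
                             comment.char = "#")
  if (ncol(tab) < 2L) stop("tabulated PES file must have two columns: x V")
  structure(list(x = tab[[1]], V = tab[[2]]),
            class = c("tabulated_pes", "psdvr_pes"))
}

#' @export
evaluate_pes.tabulated_pes <- function(pes, x) {
  stats::approx(pes$x, pes$V, xout = x, rule = 2)$y
}
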