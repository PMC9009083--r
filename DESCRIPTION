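Package: psdvr
Title: Grid-Based Vibrational Eigensolvers and Program Synthesis of Sparse
    DVR-Type Algorithms
Version: 0.1.0
Authors@R:
    person("psdvr", "maintainers", email = "psdvr@example.org", role = c("aut", "cre"))
Description: Solves the vibrational time-independent Schroedinger equation on
    uniform coordinate grids using discrete variable representation (DVR)
    Hamiltonians (Colbert-Miller and central finite differences), including
    direct-product assembly for multidimensional potentials and sparse
    symmetric eigensolution.  Also implements a program-synthesis engine that
    represents grid-based solvers as short integer sequences over a workspace
    function library, optimizes them by simulated annealing against
    wave-function and expectation-energy cost functions (with optional
    enforcement of tridiagonal matrix structure), and ships an evaluation
    harness for accuracy, convergence and sparsity benchmarking, together with
    a registry of discovered solver rules usable without any search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RSpectra,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
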