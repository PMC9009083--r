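# Registry of published-style discovered solver rules.
#
# PROVENANCE / SYNTHETIC-RECONSTRUCTION NOTICE --------------------------------
# The closed-form element rules of the originally published discovered
# algorithms appear only in typeset material (a table of working equations
# and one display equation with a constant `a`) that was not recoverable from
# the source available when this package was written.  Each entry below is
# therefore a SYNTHETIC RECONSTRUCTION: a rule with exactly the structural
# properties the surrounding prose does state -- the potential V_i occupies
# the diagonal, off-diagonal elements are decaying functions of (x_i - x_j),
# the N = 20 tridiagonal rule is exactly tridiagonal, and the lower triangle
# is authoritative at solve time.  Per-label notes:
#
#   C20Tri_E1_A : M_ii = V_i + 2a, M_{i,i+-1} = -a, a = 1/(2 m dx^2).
#                 The published constant `a` was unrecoverable; this is the
#                 unique choice for which the band reproduces a kinetic
#                 operator, and it makes the rule's eigenvectors accurate
#                 enough that expectation-route energies track the converged
#                 reference (the published behaviour).
#   C20Full_E1_A: the sinc-kernel rule written in coordinate differences:
#                 M_ii = V_i + pi^2/(6 m dx^2),
#                 M_ij = (-1)^(i-j) / (m (x_i - x_j)^2) for i != j.
#   C25Full_E1_A: the C20Full rule with every element doubled.  Same
#                 eigenvectors, doubled eigenvalues: a deliberate exemplar of
#                 why matrix eigenvalues of discovered codes are NOT energies
#                 and only the expectation route is meaningful.
#   C15Full_E1_A: the tridiagonal rule with a constant +2 diagonal shift
#                 (a leftover additive constant, as short codes tend to carry).
#                 Shifts the spectrum, leaves eigenvectors untouched.  The
#                 original N = 15 code's degraded large-grid convergence is
#                 NOT reproduced by this stand-in.
#
# Keeping all transcription in this one file means a future verbatim
# transcription only has to replace the `elements` closures below and bump
# the provenance notes; no solver logic changes.
# -----------------------------------------------------------------------------

discovered_registry <- function() {
  list(
    C20Tri_E1_A = list(
      label = "C20Tri_E1_A", structure = "tridiagonal",
      provenance = "synthetic reconstruction (see registry header)",
      elements = function(V, grid, m) {
        n <- grid$n_g
        a <- 1 / (2 * m * grid$dx^2)
        M <- diag(V + 2 * a, n)
        M[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- -a
        M[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- -a
        M
      }),
    C20Full_E1_A = list(
      label = "C20Full_E1_A", structure = "full",
      provenance = "synthetic reconstruction (see registry header)",
      elements = function(V, grid, m) {
        n <- grid$n_g
        d <- outer(seq_len(n), seq_len(n), "-")
        Dx <- outer(grid$points, grid$points, "-")
        M <- matrix(0, n, n)
        off <- d != 0
        M[off] <- (-1)^d[off] / (m * Dx[off]^2)
        diag(M) <- V + pi^2 / (6 * m * grid$dx^2)
        M
      }),
    C25Full_E1_A = list(
      label = "C25Full_E1_A", structure = "full",
      provenance = "synthetic reconstruction (see registry header)",
      elements = function(V, grid, m) {
        n <- grid$n_g
        d <- outer(seq_len(n), seq_len(n), "-")
        Dx <- outer(grid$points, grid$points, "-")
        M <- matrix(0, n, n)
        off <- d != 0
        M[off] <- 2 * (-1)^d[off] / (m * Dx[off]^2)
        diag(M) <- 2 * (V + pi^2 / (6 * m * grid$dx^2))
        M
      }),
    C15Full_E1_A = list(
      label = "C15Full_E1_A", structure = "tridiagonal",
      provenance = "synthetic reconstruction (see registry header)",
      elements = function(V, grid, m) {
        n <- grid$n_g
        a <- 1 / (2 * m * grid$dx^2)
        M <- diag(V + 2 * a + 2, n)
        M[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- -a
        M[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- -a
        M
      })
  )
}
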