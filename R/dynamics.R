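# Delta-kick perturbation and real-time propagation of the one-electron
# density matrix.  Propagation runs in the orthonormalized representation
# with an exponential-midpoint predictor and Fock-averaging corrector.

#' Delta-kick field specification
#'
#' @param strength field impulse kappa in atomic units; must be positive and
#'   small enough for linear response (default `2e-4`).
#' @param direction `"x"`, `"y"`, `"z"` or a 3-vector (normalized
#'   internally).
#' @return list of class `kick_field`.
#' @export
kick_field <- function(strength = 2e-4, direction = "x") {
  if (is.character(direction)) {
    direction <- switch(direction, x = c(1, 0, 0), y = c(0, 1, 0),
                        z = c(0, 0, 1),
                        stop("direction must be x, y, z or a 3-vector"))
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("zero kick direction")
  if (strength < 0) stop("kick strength must be non-negative")
  structure(list(strength = strength, direction = direction / nrm),
            class = "kick_field")
}

#' Apply an instantaneous dipole kick to a density matrix
#'
#' A delta pulse of field impulse kappa along the given direction multiplies
#' the occupied orbitals by `exp(-i kappa d)` where `d` is the dipole
#' operator along the kick direction; the density transforms unitarily, so
#' idempotency and the electron count are preserved exactly.
#'
#' @param density (real) converged ground-state density matrix in the AO
#'   basis.
#' @param ints an [compute_integrals()] object supplying `S` and the dipole
#'   matrices.
#' @param field a [kick_field()].
#' @return complex perturbed density matrix in the AO basis.
#' @export
apply_kick <- function(density, ints, field = kick_field()) {
  if (field$strength == 0) return(density)
  Dd <- field$direction[1] * ints$D$x + field$direction[2] * ints$D$y +
    field$direction[3] * ints$D$z
  X <- orthogonalizer(ints$S)
  Dp <- crossprod(X, Dd %*% X)
  e <- eigen((Dp + t(Dp)) / 2, symmetric = TRUE)
  U <- e$vectors %*% (exp(-1i * field$strength * e$values) *
                        t(Conj(e$vectors)))
  Y <- ints$S %*% X
  Pp <- crossprod(Y, density %*% Y)    # orthonormal representation
  Pk <- U %*% Pp %*% Conj(t(U))
  X %*% Pk %*% Conj(t(X))              # back to the AO basis
}

#' Real-time propagation of the density matrix
#'
#' Each step propagates with the exponential of the midpoint Fock matrix:
#' the predictor extrapolates the midpoint Fock linearly from the two
#' previous steps, the corrector rebuilds the Fock at the predicted density
#' and re-propagates with the average of current and new Fock until the
#' density change falls below `corrector_tol` (or `max_corrector` sweeps).
#' The total dipole, a Mulliken-symmetrized per-basis-function partition of
#' the dipole, the idempotency-trace drift and the total energy are recorded
#' at every step.
#'
#' @param density real or complex AO density matrix (e.g. from
#'   [apply_kick()]).
#' @param ints an [compute_integrals()] object.
#' @param dt time step in atomic units of time.
#' @param n_steps number of steps.
#' @param corrector_tol corrector convergence threshold on `max |dP|`.
#' @param max_corrector maximum corrector sweeps per step.
#' @param n_electrons electron count (defaults to `Tr(P S)` rounded).
#' @param kick the [kick_field()] that produced `density`, recorded as
#'   metadata.
#' @return list of class `propagation_trace`: `times` (au), `total_dipole`
#'   (`n_steps` x 3, electronic dipole in au), `per_basis` (list of three
#'   `n_steps` x nbf matrices), `drift_series`, `energy`, `dt`, `n_steps`,
#'   `duration_fs`, `basis_atom`, `atoms`, `kick`.
#' @export
propagate <- function(density, ints, dt = 0.25, n_steps = 10000,
                      corrector_tol = 1e-7, max_corrector = 10,
                      n_electrons = NULL, kick = NULL) {
  S <- ints$S
  X <- orthogonalizer(S)
  Y <- S %*% X
  P <- if (is.complex(density)) density else density + 0i
  Pp <- crossprod(Y, P %*% Y)
  if (is.null(n_electrons)) {
    n_electrons <- round(Re(sum(diag(Pp))))
  }
  res <- propagate_cpp(X, ints$Hcore, ints$eri$i, ints$eri$j, ints$eri$k,
                       ints$eri$l, ints$eri$val, ints$eri$code, Pp,
                       ints$D$x, ints$D$y, ints$D$z,
                       ints$nuclear_repulsion, n_electrons,
                       dt, n_steps, corrector_tol, max_corrector)
  structure(list(times = as.numeric(res$times),
                 total_dipole = res$dipole,
                 per_basis = list(x = res$per_basis_x, y = res$per_basis_y,
                                  z = res$per_basis_z),
                 drift_series = as.numeric(res$drift),
                 energy = as.numeric(res$energy),
                 dt = dt, n_steps = n_steps,
                 duration_fs = n_steps * dt * FS_PER_AU,
                 mean_corrector_iters = res$mean_corrector_iters,
                 basis_atom = ints$basis$atom,
                 atoms = ints$system$atoms,
                 n_electrons = n_electrons,
                 kick = kick),
            class = "propagation_trace")
}

#' @export
print.propagation_trace <- function(x, ...) {
  cat(sprintf(
    "propagation_trace: %d steps x %.3g au = %.2f fs, max trace drift %.2e e/e\n",
    x$n_steps, x$dt, x$duration_fs, trace_drift(x)))
  invisible(x)
}

#' Idempotency-trace drift of a propagation
#'
#' Largest deviation over time of `Tr((PS)^2)/2` from the electron count, per
#' electron: the numerical-stability diagnostic of the propagation.
#'
#' @param trace a [propagate()] result.
#' @return non-negative scalar, electrons per electron.
#' @export
trace_drift <- function(trace) {
  max(trace$drift_series)
}
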