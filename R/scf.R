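# Restricted Hartree-Fock ground state with DIIS acceleration, Mulliken
# population analysis, and the total-charge selection protocol (Mulliken
# ligand electron count plus a short stability propagation).

#' Restricted Hartree-Fock ground state
#'
#' DIIS-accelerated Roothaan iterations from a core-Hamiltonian guess.
#' Convergence requires the energy change below `conv_energy` Hartree and
#' the largest density-matrix change below `conv_density`.  The density
#' follows the doubly-occupied convention `Tr(P S) = n_electrons`,
#' `P S P = 2 P`.
#'
#' @param ints an [compute_integrals()] object.
#' @param n_electrons even electron count (closed-shell only).
#' @param max_iter maximum iterations.
#' @param conv_energy,conv_density convergence thresholds.
#' @param diis_size DIIS subspace dimension.
#' @return list of class `scf_result`: `energy` (Hartree, incl. nuclear
#'   repulsion), `density`, `orbitals`, `orbital_energies`, `Fock`,
#'   `converged`, `iterations`, `X` (orthogonalizer).
#' @export
run_rhf <- function(ints, n_electrons = ints$system$n_electrons,
                    max_iter = 200, conv_energy = 1e-8, conv_density = 1e-6,
                    diis_size = 8) {
  if (is.na(n_electrons)) stop("electron count is unset; assign a charge first")
  if (n_electrons %% 2 != 0) {
    stop("odd electron count (", n_electrons, "): closed-shell RHF only")
  }
  nbf <- ints$basis$n
  if (n_electrons > 2 * nbf) {
    stop("more electrons (", n_electrons, ") than the basis can hold")
  }
  nocc <- n_electrons / 2
  S <- ints$S
  X <- orthogonalizer(S)
  H <- ints$Hcore
  Fm <- H
  P <- matrix(0, nbf, nbf)
  E_old <- Inf
  err_list <- list(); fock_list <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Fp <- crossprod(X, Fm %*% X)
    e <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(e$values)
    eps <- e$values[ord]
    C <- X %*% e$vectors[, ord, drop = FALSE]
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    P_new <- 2 * tcrossprod(Cocc)
    dP <- max(abs(P_new - P))
    P <- P_new
    Fm <- fock_matrix(ints, P)
    E <- 0.5 * sum(P * (H + Fm)) + ints$nuclear_repulsion
    dE <- E - E_old
    E_old <- E
    if (abs(dE) < conv_energy && dP < conv_density) {
      converged <- TRUE
      break
    }
    # DIIS on the orthonormal-basis commutator F P S - S P F
    err <- crossprod(X, (Fm %*% P %*% S - S %*% P %*% Fm) %*% X)
    err_list <- c(err_list, list(err))
    fock_list <- c(fock_list, list(Fm))
    if (length(err_list) > diis_size) {
      err_list <- err_list[-1]; fock_list <- fock_list[-1]
    }
    m <- length(err_list)
    if (m >= 2) {
      B <- matrix(0, m + 1, m + 1)
      for (a in seq_len(m)) for (b in seq_len(m)) {
        B[a, b] <- sum(err_list[[a]] * err_list[[b]])
      }
      B[m + 1, seq_len(m)] <- B[seq_len(m), m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        Fm <- Reduce(`+`, Map(`*`, fock_list, cf))
      }
    }
  }
  if (!converged) {
    stop(sprintf(
      "SCF did not converge in %d iterations (last dE = %.3e Ha, max |dP| = %.3e)",
      max_iter, dE, dP))
  }
  structure(list(energy = E, density = P, orbitals = C,
                 orbital_energies = eps, Fock = Fm, converged = converged,
                 iterations = it, X = X, n_electrons = n_electrons),
            class = "scf_result")
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("RHF: E = %.8f Ha, %d electrons, %s in %d iterations\n",
              x$energy, x$n_electrons,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Mulliken population analysis
#'
#' Partitions the electrons among atoms via the diagonal of `P S`; per-atom
#' counts sum exactly to `Tr(P S)`.
#'
#' @param P density matrix (AO basis, doubly-occupied convention).
#' @param S overlap matrix.
#' @param basis_atom 1-based atom index for every basis function (the `atom`
#'   field of [build_basis()]).
#' @param n_atoms number of atoms (defaults to `max(basis_atom)`).
#' @return numeric vector of per-atom electron counts.
#' @export
mulliken <- function(P, S, basis_atom, n_atoms = max(basis_atom)) {
  gross <- Re(rowSums(P * t(S)))   # diag(P %*% S)
  as.numeric(tapply(gross, factor(basis_atom, levels = seq_len(n_atoms)), sum,
                    default = 0))
}

#' Select the total charge of a carved system
#'
#' For each candidate charge (even electron counts only) the ground state is
#' solved, the Mulliken electron count of the ligand fragment is evaluated,
#' and a short field-free propagation probes numerical stability via the
#' idempotency-trace drift.  Candidates whose ligand electron count falls in
#' `[target - 0.5, target]` are accepted; among those the smallest trace
#' drift wins, with ties broken towards the charge closest to zero and then
#' towards the negative one.
#'
#' @param system a [molecular_system()] (charge may be unset).
#' @param ligand_indices atom indices of the ligand fragment.
#' @param candidates integer vector of candidate total charges.
#' @param target_electrons intended ligand electron count (408 for the
#'   oxidized FAD dianion).
#' @param test_steps number of field-free test propagation steps.
#' @param dt time step (atomic units) for the test propagation.
#' @param window half-open acceptance window width below `target_electrons`.
#' @param screen_threshold passed to [compute_integrals()].
#' @param ... further arguments for [run_rhf()].
#' @return list with `charge` (chosen), `scan` (data frame: candidate_charge,
#'   n_electrons, ligand_electrons, trace_drift, in_window, stable).
#' @export
select_charge <- function(system, ligand_indices, candidates,
                          target_electrons, test_steps = 50, dt = 0.25,
                          window = 0.5, screen_threshold = 1e-6, ...) {
  atoms <- system$atoms
  sumZ <- sum(atomic_number(atoms$element))
  ints <- compute_integrals(
    molecular_system(atoms, total_charge = 0L, label = system$label),
    screen_threshold = screen_threshold)
  rows <- list()
  for (q in candidates) {
    ne <- sumZ - q
    if (ne %% 2 != 0) {
      warning("skipping charge ", q, ": odd electron count ", ne)
      next
    }
    res <- tryCatch(run_rhf(ints, n_electrons = ne, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1]] <- data.frame(
        candidate_charge = q, n_electrons = ne, ligand_electrons = NA_real_,
        trace_drift = Inf, in_window = FALSE, stable = FALSE)
      next
    }
    pops <- mulliken(res$density, ints$S, ints$basis$atom, nrow(atoms))
    lig_el <- sum(pops[ligand_indices])
    tr <- propagate(res$density, ints, dt = dt, n_steps = test_steps,
                    n_electrons = ne)
    drift <- trace_drift(tr)
    rows[[length(rows) + 1]] <- data.frame(
      candidate_charge = q, n_electrons = ne, ligand_electrons = lig_el,
      trace_drift = drift,
      in_window = lig_el >= target_electrons - window - 1e-9 &
        lig_el <= target_electrons + 1e-9,
      stable = is.finite(drift) && drift < 1e-6)
  }
  scan <- do.call(rbind, rows)
  ok <- which(scan$in_window)
  if (length(ok) == 0) {
    stop("no candidate charge gives a ligand electron count in [",
         target_electrons - window, ", ", target_electrons, "]; scan table:\n",
         paste(utils::capture.output(print(scan)), collapse = "\n"))
  }
  # drifts below the numerical noise floor count as ties
  dr <- pmax(scan$trace_drift[ok], 1e-9)
  ord <- ok[order(dr, abs(scan$candidate_charge[ok]),
                  scan$candidate_charge[ok])]
  list(charge = scan$candidate_charge[ord[1]], scan = scan)
}
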