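# One- and two-electron integrals in atomic units over the STO-3G basis.
# Heavy lifting happens in compiled code (McMurchie-Davidson recurrences);
# these wrappers fix conventions: dipole origin at the nuclear center of
# charge, Schwarz screening of two-electron quantities at `screen_threshold`.

.nuclear_geometry <- function(system) {
  atoms <- if (inherits(system, "molecular_system")) system$atoms else
    .as_atom_frame(system)
  Z <- atomic_number(atoms$element)
  pos <- as.matrix(atoms[, c("x", "y", "z")]) * ANGSTROM_TO_BOHR
  list(Z = Z, pos = pos, origin = colSums(Z * pos) / sum(Z))
}

#' One-electron integrals and nuclear repulsion
#'
#' Computes overlap `S`, kinetic `T`, nuclear attraction `V`, the three
#' dipole-operator matrices `D` (origin at the nuclear center of charge) and
#' the nuclear repulsion energy, all in atomic units.
#'
#' @param basis an [build_basis()] object.
#' @param system the [molecular_system()] the basis was built for.
#' @return list with `S`, `T`, `V`, `D` (list `x`, `y`, `z`),
#'   `nuclear_repulsion` (Hartree) and `origin` (bohr).
#' @export
one_electron_integrals <- function(basis, system) {
  g <- .nuclear_geometry(system)
  res <- one_electron_cpp(basis, g$Z, g$pos, g$origin)
  nat <- length(g$Z)
  enuc <- 0
  if (nat > 1) {
    d <- as.matrix(dist(g$pos))
    enuc <- sum(outer(g$Z, g$Z)[upper.tri(d)] / d[upper.tri(d)])
  }
  list(S = res$S, T = res$T, V = res$V,
       D = list(x = res$Dx, y = res$Dy, z = res$Dz),
       nuclear_repulsion = enuc, origin = g$origin)
}

#' Screened two-electron integrals
#'
#' A basis-function pair is significant when its Schwarz factor
#' `sqrt((mu nu|mu nu))` times the largest Schwarz factor reaches
#' `screen_threshold`.  Integrals are computed and stored for quartets of
#' significant pairs whose Schwarz product reaches the threshold; no further
#' distance-based truncation is applied when contracting the Coulomb or
#' exchange terms.
#'
#' @param basis an [build_basis()] object.
#' @param screen_threshold significance threshold (dimensionless), default
#'   `1e-6`; `0` disables screening.
#' @param memory_budget_gb abort with an estimate if the quartet store would
#'   exceed this budget.
#' @return list of class `eri_store` with 0-based index vectors `i,j,k,l`,
#'   values `val`, degeneracy `code`, the significant-pair table and counts.
#' @export
two_electron_integrals <- function(basis, screen_threshold = 1e-6,
                                   memory_budget_gb = 4) {
  out <- eri_screened_cpp(basis, screen_threshold, memory_budget_gb)
  out$screen_threshold <- screen_threshold
  out$n <- basis$n
  class(out) <- "eri_store"
  out
}

#' Dense unscreened two-electron tensor (small-system reference)
#'
#' Full `n^4` array with exact 8-fold permutational symmetry; restricted to
#' small basis sets, intended as the unscreened reference.
#'
#' @param basis an [build_basis()] object (at most ~30 functions).
#' @return numeric array of dimension `c(n, n, n, n)`.
#' @export
eri_dense <- function(basis) {
  eri_dense_cpp(basis)
}

#' All integrals for a system
#'
#' Convenience wrapper building the basis and all integral blocks.
#'
#' @param system a [molecular_system()].
#' @param screen_threshold Schwarz screening threshold for two-electron
#'   quantities.
#' @param memory_budget_gb memory budget for the quartet store.
#' @return list of class `integral_set` with `basis`, `S`, `T`, `V`, `D`,
#'   `Hcore`, `eri`, `nuclear_repulsion`, `system`.
#' @export
compute_integrals <- function(system, screen_threshold = 1e-6,
                              memory_budget_gb = 4) {
  basis <- build_basis(system)
  one <- one_electron_integrals(basis, system)
  eri <- two_electron_integrals(basis, screen_threshold, memory_budget_gb)
  structure(list(basis = basis, S = one$S, T = one$T, V = one$V, D = one$D,
                 Hcore = one$T + one$V, eri = eri,
                 nuclear_repulsion = one$nuclear_repulsion,
                 origin = one$origin, system = system),
            class = "integral_set")
}

#' @export
print.integral_set <- function(x, ...) {
  cat(sprintf(
    "integral_set: %d basis functions, %d significant pairs, %.0f stored quartets\n",
    x$basis$n, nrow(x$eri$sig_pairs), x$eri$n_quartets))
  invisible(x)
}

# Fock matrix F = Hcore + J - K/2 from the quartet store; P may be complex
# (the antisymmetric imaginary part only contributes to exchange).
fock_matrix <- function(ints, P) {
  Pre <- Re(P)
  Pim <- if (is.complex(P)) Im(P) else NULL
  jk <- fock_jk_cpp(ints$eri$n, ints$eri$i, ints$eri$j, ints$eri$k,
                    ints$eri$l, ints$eri$val, ints$eri$code, Pre, Pim)
  Fre <- ints$Hcore + jk$J - 0.5 * jk$Kre
  if (is.null(Pim)) return(Fre)
  Fre - 0.5i * jk$Kim
}

# Canonical orthogonalization X: overlap eigenvectors scaled by 1/sqrt(s),
# eigenvalues below `tol` projected out (linear-dependence handling).
orthogonalizer <- function(S, tol = 1e-7) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol
  if (!any(keep)) stop("overlap matrix is numerically singular")
  e$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(e$values[keep]),
                                           nrow = sum(keep))
}
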