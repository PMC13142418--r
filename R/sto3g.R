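# STO-3G basis parameters.  Each Slater-type orbital is expanded in three
# primitive Gaussians; 2s/2p (and 3s/3p) shells share exponents.  Contraction
# coefficients refer to normalized primitives; contracted functions are
# rescaled to unit self-overlap when the basis is built.

.sto3g_coef <- list(
  s1 = c(0.1543289673, 0.5353281423, 0.4446345422),
  s2 = c(-0.09996722919, 0.3995128261, 0.7001154689),
  p2 = c(0.1559162750, 0.6076837186, 0.3919573931),
  s3 = c(-0.2196203690, 0.2255954336, 0.9003984260),
  p3 = c(0.01058760429, 0.5951670053, 0.4620010120)
)

# shells: list of (type, exponents); type "s" or "sp" with principal number
.sto3g_shells <- list(
  H = list(list(n = 1, exp = c(3.425250914, 0.6239137298, 0.1688554040))),
  He = list(list(n = 1, exp = c(6.362421394, 1.158922999, 0.3136497915))),
  C = list(list(n = 1, exp = c(71.61683735, 13.04509632, 3.530512160)),
           list(n = 2, exp = c(2.941249355, 0.6834830964, 0.2222899159))),
  N = list(list(n = 1, exp = c(99.10616896, 18.05231239, 4.885660238)),
           list(n = 2, exp = c(3.780455879, 0.8784966449, 0.2857143744))),
  O = list(list(n = 1, exp = c(130.7093214, 23.80886605, 6.443608313)),
           list(n = 2, exp = c(5.033151319, 1.169596125, 0.3803889600))),
  P = list(list(n = 1, exp = c(468.3656378, 85.31338559, 23.08913156)),
           list(n = 2, exp = c(28.03263958, 6.514182577, 2.116175612)),
           list(n = 3, exp = c(1.743103231, 0.5785947429, 0.2100046880))),
  S = list(list(n = 1, exp = c(533.1257359, 97.10951830, 26.28162542)),
           list(n = 2, exp = c(33.32975173, 7.745117521, 2.518952599)),
           list(n = 3, exp = c(2.029194274, 0.5661400518, 0.2215833792)))
)

# number of basis functions per element (1s for n=1; s + 3 p for n >= 2)
.sto3g_count <- vapply(.sto3g_shells, function(sh) {
  sum(vapply(sh, function(s) if (s$n == 1) 1L else 4L, integer(1)))
}, integer(1))

# normalization constant of a primitive Cartesian Gaussian x^l y^m z^n e^{-a r^2}
.prim_norm <- function(a, l, m, n) {
  dfact <- function(k) if (k <= 1) 1 else prod(seq(k, 1, by = -2))
  (2 * a / pi)^0.75 * (4 * a)^((l + m + n) / 2) /
    sqrt(dfact(2 * l - 1) * dfact(2 * m - 1) * dfact(2 * n - 1))
}

#' Build the STO-3G basis for a molecular system
#'
#' One contracted function per Slater orbital: H/He carry a single 1s
#' function; first-row atoms 1s, 2s, 2px, 2py, 2pz; P and S additionally
#' 3s, 3px, 3py, 3pz.  Functions are ordered by atom, then by shell, with
#' Cartesian p components in x, y, z order.  Contracted functions are
#' normalized to unit self-overlap.
#'
#' @param system a [molecular_system()] (or a bare atom data frame with
#'   `element`, `x`, `y`, `z` columns in Angstrom).
#' @return an object of class `rthf_basis`: a list with per-function vectors
#'   `atom` (1-based atom index), `label`, integer matrix `lmn` (Cartesian
#'   exponents), and matrices `centers` (bohr), `exps`, `coefs` (3 primitives
#'   per function).
#' @export
build_basis <- function(system) {
  atoms <- if (inherits(system, "molecular_system")) system$atoms else system
  missing_el <- setdiff(unique(atoms$element), names(.sto3g_shells))
  if (length(missing_el) > 0) {
    stop("no STO-3G parameters for element(s): ",
         paste(missing_el, collapse = ", "))
  }
  atom_i <- integer(0); label <- character(0)
  lmn <- matrix(integer(0), ncol = 3)
  exps <- coefs <- matrix(numeric(0), ncol = 3)
  centers <- matrix(numeric(0), ncol = 3)
  for (a in seq_len(nrow(atoms))) {
    el <- atoms$element[a]
    cen <- c(atoms$x[a], atoms$y[a], atoms$z[a]) * ANGSTROM_TO_BOHR
    for (sh in .sto3g_shells[[el]]) {
      stypes <- if (sh$n == 1) list(list(l = c(0L, 0L, 0L), lab = "1s"))
      else {
        sl <- paste0(sh$n, "s"); pl <- paste0(sh$n, "p")
        list(list(l = c(0L, 0L, 0L), lab = sl),
             list(l = c(1L, 0L, 0L), lab = paste0(pl, "x")),
             list(l = c(0L, 1L, 0L), lab = paste0(pl, "y")),
             list(l = c(0L, 0L, 1L), lab = paste0(pl, "z")))
      }
      cs <- if (sh$n == 1) .sto3g_coef$s1
      else if (sh$n == 2) list(.sto3g_coef$s2, .sto3g_coef$p2)
      else list(.sto3g_coef$s3, .sto3g_coef$p3)
      for (st in stypes) {
        cc <- if (sh$n == 1) cs else if (st$lab %in% c("2s", "3s")) cs[[1]] else cs[[2]]
        nrm <- vapply(sh$exp, .prim_norm, numeric(1),
                      l = st$l[1], m = st$l[2], n = st$l[3])
        atom_i <- c(atom_i, a)
        label <- c(label, st$lab)
        lmn <- rbind(lmn, st$l)
        centers <- rbind(centers, cen)
        exps <- rbind(exps, sh$exp)
        coefs <- rbind(coefs, cc * nrm)
      }
    }
  }
  basis <- list(atom = atom_i, label = label, lmn = lmn, centers = centers,
                exps = exps, coefs = coefs)
  # rescale to exact unit self-overlap (the tabulated contractions are only
  # normalized to ~1e-4)
  s <- as.numeric(self_overlaps_cpp(basis))
  basis$coefs <- basis$coefs / sqrt(s)
  basis$n <- length(atom_i)
  class(basis) <- "rthf_basis"
  basis
}

#' @export
print.rthf_basis <- function(x, ...) {
  cat("STO-3G basis:", x$n, "functions on", max(x$atom), "atoms\n")
  invisible(x)
}
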