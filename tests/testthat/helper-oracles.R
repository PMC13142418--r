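# Independent oracles used across the suite.  These deliberately avoid the
# package's McMurchie-Davidson/Fock machinery: one-electron integrals are
# evaluated by Gauss-Hermite quadrature of the actual primitive products
# (with the Coulomb kernel handled through its Gaussian-transform
# representation), s-function repulsion integrals come from the erf-based
# closed form, the reference SCF is a damped fixed-point loop over the dense
# unscreened tensor, and excitation energies come from explicit
# linear-response TDHF diagonalization.

.gh_cache <- new.env()
gh_nodes <- function(n = 24) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(n)
  .gh_cache[[key]]
}

# 1-D primitive factor (x - A)^l exp(-a (x - A)^2) and its second derivative
g1 <- function(x, l, a, A) (x - A)^l * exp(-a * (x - A)^2)
g1dd <- function(x, l, a, A) {
  s <- x - A
  core <- 4 * a^2 * s^(l + 2) - 2 * a * (2 * l + 1) * s^l
  if (l >= 2) core <- core + l * (l - 1) * s^(l - 2)
  core * exp(-a * s^2)
}

# integral over one dimension of f1 * f2 (* optional extra Gaussian
# exp(-u2 (x - C)^2)) by Gauss-Hermite quadrature on the combined Gaussian
gh_1d <- function(l1, a, A, l2, b, B, f2dd = FALSE, xop = 0, u2 = 0, C = 0) {
  p <- a + b + u2
  P <- (a * A + b * B + u2 * C) / p
  gh <- gh_nodes()
  x <- P + gh$x / sqrt(p)
  f1 <- g1(x, l1, a, A)
  f2 <- if (f2dd) g1dd(x, l2, b, B) else g1(x, l2, b, B)
  extra <- if (u2 > 0) exp(-u2 * (x - C)^2) else 1
  opf <- if (xop > 0) x^xop else 1
  # remove the Gaussian weight the GH rule supplies
  sum(gh$w * f1 * f2 * extra * opf * exp(p * (x - P)^2)) / sqrt(p)
}

# contracted one-electron integrals by quadrature.  type: "S", "T",
# "Dx"/"Dy"/"Dz" (dipole about `origin`), or "V" (sum over nuclei)
quad_one_electron <- function(basis, i, j, type, Z = NULL, nucpos = NULL,
                              origin = c(0, 0, 0)) {
  li <- basis$lmn[i, ]; lj <- basis$lmn[j, ]
  A <- basis$centers[i, ]; B <- basis$centers[j, ]
  total <- 0
  for (p in 1:3) for (q in 1:3) {
    a <- basis$exps[i, p]; b <- basis$exps[j, q]
    cc <- basis$coefs[i, p] * basis$coefs[j, q]
    if (type == "S") {
      v <- prod(vapply(1:3, function(d)
        gh_1d(li[d], a, A[d], lj[d], b, B[d]), numeric(1)))
    } else if (type == "T") {
      s1d <- vapply(1:3, function(d)
        gh_1d(li[d], a, A[d], lj[d], b, B[d]), numeric(1))
      t1d <- vapply(1:3, function(d)
        gh_1d(li[d], a, A[d], lj[d], b, B[d], f2dd = TRUE), numeric(1))
      v <- -0.5 * (t1d[1] * s1d[2] * s1d[3] + s1d[1] * t1d[2] * s1d[3] +
                     s1d[1] * s1d[2] * t1d[3])
    } else if (type %in% c("Dx", "Dy", "Dz")) {
      dd <- match(type, c("Dx", "Dy", "Dz"))
      v <- prod(vapply(1:3, function(d) {
        base <- gh_1d(li[d], a, A[d], lj[d], b, B[d],
                      xop = if (d == dd) 1 else 0)
        base
      }, numeric(1)))
      # subtract origin * overlap in the operator dimension
      sdims <- vapply(1:3, function(d)
        gh_1d(li[d], a, A[d], lj[d], b, B[d]), numeric(1))
      v <- v - origin[dd] * prod(sdims)
    } else if (type == "V") {
      v <- 0
      for (at in seq_along(Z)) {
        C <- nucpos[at, ]
        inner <- function(u) {
          vapply(u, function(uu) {
            prod(vapply(1:3, function(d)
              gh_1d(li[d], a, A[d], lj[d], b, B[d],
                    u2 = uu^2, C = C[d]), numeric(1)))
          }, numeric(1))
        }
        iu <- stats::integrate(inner, 0, Inf, rel.tol = 1e-10,
                               abs.tol = 1e-12)$value
        v <- v - Z[at] * 2 / sqrt(pi) * iu
      }
    } else stop("unknown type")
    total <- total + cc * v
  }
  total
}

# closed-form (ab|cd) for contracted s functions, via erf (pnorm)
boys0 <- function(x) ifelse(x < 1e-12, 1 - x / 3,
                            0.5 * sqrt(pi / x) * (2 * stats::pnorm(sqrt(2 * x)) - 1))
eri_s_closed <- function(basis, i, j, k, l) {
  stopifnot(all(basis$lmn[c(i, j, k, l), ] == 0))
  A <- basis$centers[i, ]; B <- basis$centers[j, ]
  Cc <- basis$centers[k, ]; Dd <- basis$centers[l, ]
  total <- 0
  for (pp in 1:3) for (qq in 1:3) for (rr in 1:3) for (ss in 1:3) {
    a <- basis$exps[i, pp]; b <- basis$exps[j, qq]
    c2 <- basis$exps[k, rr]; d2 <- basis$exps[l, ss]
    coef <- basis$coefs[i, pp] * basis$coefs[j, qq] *
      basis$coefs[k, rr] * basis$coefs[l, ss]
    p <- a + b; q <- c2 + d2
    P <- (a * A + b * B) / p; Q <- (c2 * Cc + d2 * Dd) / q
    pref <- 2 * pi^2.5 / (p * q * sqrt(p + q)) *
      exp(-a * b / p * sum((A - B)^2) - c2 * d2 / q * sum((Cc - Dd)^2))
    alpha <- p * q / (p + q)
    total <- total + coef * pref * boys0(alpha * sum((P - Q)^2))
  }
  total
}

# general quadrature oracle for electron-repulsion integrals: the Coulomb
# kernel is written as a Gaussian transform, 1/r12 = 2/sqrt(pi) int du
# exp(-u^2 r12^2); for each u the six-dimensional integral factorizes per
# dimension into correlated 2-D Gaussians, which are diagonalized and
# integrated exactly by Gauss-Hermite after rotation
quad_eri <- function(basis, i, j, k, l) {
  gh <- gh_nodes(10)
  t2 <- expand.grid(t1 = gh$x, t2 = gh$x)
  w2 <- outer(gh$w, gh$w)
  dim(w2) <- NULL
  li <- basis$lmn[i, ]; lj <- basis$lmn[j, ]
  lk <- basis$lmn[k, ]; ll <- basis$lmn[l, ]
  A <- basis$centers[i, ]; B <- basis$centers[j, ]
  Cc <- basis$centers[k, ]; Dd <- basis$centers[l, ]
  pair_int_1d <- function(u2, a, b, c2, d2, Ax, Bx, Cx, Dx, la, lb, lc, ld) {
    Q <- matrix(c(a + b + u2, -u2, -u2, c2 + d2 + u2), 2, 2)
    v <- c(a * Ax + b * Bx, c2 * Cx + d2 * Dx)
    m <- solve(Q, v)
    cst <- a * Ax^2 + b * Bx^2 + c2 * Cx^2 + d2 * Dx^2 - sum(m * (Q %*% m))
    eq <- eigen(Q, symmetric = TRUE)
    xy <- t(m + eq$vectors %*% (t(as.matrix(t2)) / sqrt(eq$values)))
    poly <- (xy[, 1] - Ax)^la * (xy[, 1] - Bx)^lb *
      (xy[, 2] - Cx)^lc * (xy[, 2] - Dx)^ld
    sum(w2 * poly) * exp(-cst) / sqrt(prod(eq$values))
  }
  inner <- function(u) {
    vapply(u, function(uu) {
      u2 <- uu^2
      tot <- 0
      for (pp in 1:3) for (qq in 1:3) for (rr in 1:3) for (ss in 1:3) {
        a <- basis$exps[i, pp]; b <- basis$exps[j, qq]
        c2 <- basis$exps[k, rr]; d2 <- basis$exps[l, ss]
        coef <- basis$coefs[i, pp] * basis$coefs[j, qq] *
          basis$coefs[k, rr] * basis$coefs[l, ss]
        val <- 1
        for (d in 1:3) {
          val <- val * pair_int_1d(u2, a, b, c2, d2, A[d], B[d], Cc[d], Dd[d],
                                   li[d], lj[d], lk[d], ll[d])
        }
        tot <- tot + coef * val
      }
      tot
    }, numeric(1))
  }
  2 / sqrt(pi) * stats::integrate(inner, 0, Inf, rel.tol = 1e-9,
                                  abs.tol = 1e-11)$value
}

# damped fixed-point SCF over the dense unscreened tensor (no DIIS, no
# screening; independent of the package's Fock/convergence path)
oracle_scf <- function(system, n_electrons = system$n_electrons,
                       max_iter = 500, tol = 1e-10) {
  basis <- build_basis(system)
  one <- one_electron_integrals(basis, system)
  eri <- eri_dense(basis)
  n <- basis$n
  M1 <- matrix(eri, n * n, n * n)                       # (mn|ls)
  M2 <- matrix(aperm(eri, c(1, 3, 2, 4)), n * n, n * n) # (ml|ns)
  H <- one$T + one$V
  S <- one$S
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), n)
  nocc <- n_electrons / 2
  P <- matrix(0, n, n)
  E_old <- Inf
  for (it in seq_len(max_iter)) {
    Fm <- H + matrix(M1 %*% as.vector(P), n, n) -
      0.5 * matrix(M2 %*% as.vector(P), n, n)
    E <- 0.5 * sum(P * (H + Fm)) + one$nuclear_repulsion
    Fp <- crossprod(X, Fm %*% X)
    ev <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(ev$values)
    C <- X %*% ev$vectors[, ord, drop = FALSE]
    Pn <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
    P <- 0.6 * Pn + 0.4 * P
    if (abs(E - E_old) < tol && it > 5) break
    E_old <- E
  }
  list(energy = E, density = Pn, orbitals = C,
       orbital_energies = ev$values[ord], S = S, eri = eri, Hcore = H,
       X = X, nocc = nocc)
}

# singlet excitation energies from explicit linear-response TDHF
# diagonalization (closed shell), usable for small systems
oracle_lr_tdhf <- function(system, n_electrons = system$n_electrons) {
  ref <- oracle_scf(system, n_electrons)
  n <- nrow(ref$S)
  C <- ref$orbitals
  eri_mo <- array(0, rep(n, 4))
  half <- array(0, rep(n, 4))
  # two-step half transforms (fine for tiny n)
  for (p in 1:n) for (q in 1:n) for (r in 1:n) for (s in 1:n) {
    half[p, q, r, s] <- sum(C[, p] * ref$eri[, q, r, s])
  }
  tmp <- half
  for (q in 1:n) for (r in 1:n) for (s in 1:n) {
    half[, q, r, s] <- 0
    for (b in 1:n) half[, q, r, s] <- half[, q, r, s] + C[b, q] * tmp[, b, r, s]
  }
  tmp <- half
  for (r in 1:n) for (s in 1:n) {
    half[, , r, s] <- 0
    for (cc in 1:n) half[, , r, s] <- half[, , r, s] + C[cc, r] * tmp[, , cc, s]
  }
  tmp <- half
  for (s in 1:n) {
    half[, , , s] <- 0
    for (d in 1:n) half[, , , s] <- half[, , , s] + C[d, s] * tmp[, , , d]
  }
  eri_mo <- half
  occ <- seq_len(ref$nocc)
  vir <- setdiff(seq_len(n), occ)
  nov <- length(occ) * length(vir)
  A <- matrix(0, nov, nov); B <- matrix(0, nov, nov)
  idx <- 0
  pairs <- list()
  for (i in occ) for (a in vir) {
    idx <- idx + 1
    pairs[[idx]] <- c(i, a)
  }
  for (r in seq_len(nov)) for (s in seq_len(nov)) {
    i <- pairs[[r]][1]; a <- pairs[[r]][2]
    j <- pairs[[s]][1]; b <- pairs[[s]][2]
    A[r, s] <- (r == s) * (ref$orbital_energies[a] - ref$orbital_energies[i]) +
      2 * eri_mo[i, a, j, b] - eri_mo[i, j, a, b]
    B[r, s] <- 2 * eri_mo[i, a, j, b] - eri_mo[i, b, j, a]
  }
  M <- (A - B) %*% (A + B)
  sqrt(sort(Re(eigen(M)$values)))
}

# convenience: three-direction kick + propagation + spectrum
rt_spectrum <- function(ints, scf, kick_strength = 2e-4, n_steps = 1500,
                        dt = 0.25, attenuation = 0.015,
                        energies = seq(1, 10, by = 0.0025) / 27.211386245) {
  traces <- lapply(c("x", "y", "z"), function(d) {
    P1 <- apply_kick(scf$density, ints, kick_field(kick_strength, d))
    propagate(P1, ints, dt = dt, n_steps = n_steps)
  })
  names(traces) <- c("x", "y", "z")
  list(traces = traces,
       spectrum = absorption(traces, kick_strength, attenuation,
                             energies = energies))
}
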