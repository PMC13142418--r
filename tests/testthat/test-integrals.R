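# Basis construction and integral evaluation against independent oracles.

test_that("basis sizes follow the STO-3G element table", {
  expect_equal(build_basis(toy_geometry("H2O"))$n, 7L)
  expect_equal(build_basis(toy_geometry("tryptophan"))$n, 87L)
  expect_equal(build_basis(toy_geometry("FAD_oxidized"))$n, 304L)
  expect_error(build_basis(data.frame(element = "Fe", x = 0, y = 0, z = 0)),
               "no STO-3G parameters")
})

test_that("contracted functions are normalized and S is symmetric", {
  sys <- toy_geometry("H2O")
  b <- build_basis(sys)
  one <- one_electron_integrals(b, sys)
  expect_lt(max(abs(diag(one$S) - 1)), 1e-10)
  expect_lt(max(abs(one$S - t(one$S))), 1e-12)
  expect_lt(max(abs(one$T - t(one$T))), 1e-12)
  expect_lt(max(abs(one$V - t(one$V))), 1e-12)
})

test_that("one-electron integrals match the quadrature oracle", {
  for (name in c("H2", "HeH+", "H2O")) {
    sys <- toy_geometry(name)
    b <- build_basis(sys)
    one <- one_electron_integrals(b, sys)
    g <- rthf:::.nuclear_geometry(sys)
    n <- b$n
    pairs <- cbind(rep(1:n, each = n), rep(1:n, times = n))
    pairs <- pairs[pairs[, 1] <= pairs[, 2], , drop = FALSE]
    # sample a representative subset for the expensive Coulomb oracle
    vsel <- pairs[seq(1, nrow(pairs), length.out = min(6, nrow(pairs))), ,
                  drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      expect_equal(one$S[i, j], quad_one_electron(b, i, j, "S"),
                   tolerance = 1e-6, ignore_attr = TRUE)
      expect_equal(one$T[i, j], quad_one_electron(b, i, j, "T"),
                   tolerance = 1e-6, ignore_attr = TRUE)
      expect_equal(one$D$x[i, j],
                   quad_one_electron(b, i, j, "Dx", origin = g$origin),
                   tolerance = 1e-6, ignore_attr = TRUE)
      expect_equal(one$D$z[i, j],
                   quad_one_electron(b, i, j, "Dz", origin = g$origin),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
    for (r in seq_len(nrow(vsel))) {
      i <- vsel[r, 1]; j <- vsel[r, 2]
      expect_equal(one$V[i, j],
                   quad_one_electron(b, i, j, "V", Z = g$Z, nucpos = g$pos),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("s-function repulsion integrals match the closed form", {
  he <- toy_geometry("He")
  b <- build_basis(he)
  eri <- eri_dense(b)
  expect_equal(eri[1, 1, 1, 1], eri_s_closed(b, 1, 1, 1, 1), tolerance = 1e-6)
  h2 <- toy_geometry("H2")
  b2 <- build_basis(h2)
  eri2 <- eri_dense(b2)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
    expect_equal(eri2[i, j, k, l], eri_s_closed(b2, i, j, k, l),
                 tolerance = 1e-6)
  }
})

test_that("the screened store reproduces the dense tensor on H2O", {
  sys <- toy_geometry("H2O")
  b <- build_basis(sys)
  dense <- eri_dense(b)
  store <- two_electron_integrals(b, screen_threshold = 0)
  n <- b$n
  rebuilt <- array(0, rep(n, 4))
  for (q in seq_along(store$val)) {
    i <- store$i[q] + 1; j <- store$j[q] + 1
    k <- store$k[q] + 1; l <- store$l[q] + 1
    v <- store$val[q]
    rebuilt[i, j, k, l] <- rebuilt[j, i, k, l] <- rebuilt[i, j, l, k] <-
      rebuilt[j, i, l, k] <- rebuilt[k, l, i, j] <- rebuilt[l, k, i, j] <-
      rebuilt[k, l, j, i] <- rebuilt[l, k, j, i] <- v
  }
  expect_lt(max(abs(rebuilt - dense)), 1e-12)
})

test_that("Fock contraction from the quartet store matches dense einsum", {
  sys <- toy_geometry("H2O")
  b <- build_basis(sys)
  dense <- eri_dense(b)
  store <- two_electron_integrals(b, screen_threshold = 0)
  n <- b$n
  M1 <- matrix(dense, n * n, n * n)
  M2 <- matrix(aperm(dense, c(1, 3, 2, 4)), n * n, n * n)
  set.seed(42)
  A <- matrix(rnorm(n * n), n)
  Pre <- A + t(A)
  Bm <- matrix(rnorm(n * n), n)
  Pim <- Bm - t(Bm)
  jk <- rthf:::fock_jk_cpp(n, store$i, store$j, store$k, store$l, store$val,
                           store$code, Pre, Pim)
  Jref <- matrix(M1 %*% as.vector(Pre), n, n)
  Kref_re <- matrix(M2 %*% as.vector(Pre), n, n)
  Kref_im <- matrix(M2 %*% as.vector(Pim), n, n)
  expect_lt(max(abs(jk$J - Jref)), 1e-10)
  expect_lt(max(abs(jk$Kre - Kref_re)), 1e-10)
  expect_lt(max(abs(jk$Kim - Kref_im)), 1e-10)
})

test_that("integrals are invariant under rigid translation", {
  sys <- toy_geometry("H2O")
  moved <- sys$atoms
  moved[, c("x", "y", "z")] <- moved[, c("x", "y", "z")] + 5
  sys2 <- molecular_system(moved, 0L, "moved")
  b1 <- build_basis(sys); b2 <- build_basis(sys2)
  o1 <- one_electron_integrals(b1, sys)
  o2 <- one_electron_integrals(b2, sys2)
  expect_lt(max(abs(o1$S - o2$S)), 1e-10)
  expect_lt(max(abs(o1$T - o2$T)), 1e-10)
  expect_lt(max(abs(o1$V - o2$V)), 1e-9)
  # dipole origin rides with the nuclear center of charge
  expect_lt(max(abs(o1$D$x - o2$D$x)), 1e-9)
  expect_lt(max(abs(eri_dense(b1) - eri_dense(b2))), 1e-10)
})

test_that("screening at 1e-6 changes the ground-state energy below 1e-6 Ha", {
  sys <- toy_geometry("H2O")
  e_scr <- run_rhf(compute_integrals(sys, screen_threshold = 1e-6))$energy
  e_ref <- run_rhf(compute_integrals(sys, screen_threshold = 0))$energy
  expect_lt(abs(e_scr - e_ref), 1e-6)
})

test_that("an insufficient memory budget aborts with an estimate", {
  b <- build_basis(toy_geometry("H2O"))
  expect_error(two_electron_integrals(b, memory_budget_gb = 1e-8),
               "memory budget")
})
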