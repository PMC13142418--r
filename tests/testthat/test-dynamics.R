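# Delta kick and real-time propagation: conservation laws, stability, and
# agreement with explicit linear-response theory.

test_that("a zero-strength kick leaves the density untouched", {
  sys <- toy_geometry("H2")
  ints <- compute_integrals(sys)
  res <- run_rhf(ints)
  expect_identical(apply_kick(res$density, ints, kick_field(0, "x")),
                   res$density)
})

test_that("the kick is unitary: electron count and idempotency survive", {
  sys <- toy_geometry("H2O")
  ints <- compute_integrals(sys)
  res <- run_rhf(ints)
  P1 <- apply_kick(res$density, ints, kick_field(5e-3, "z"))
  expect_equal(Re(sum(P1 * t(ints$S))), 10, tolerance = 1e-10)
  PSP <- P1 %*% ints$S %*% P1
  expect_lt(max(Mod(PSP - 2 * P1)), 1e-6)
})

test_that("the first-step dipole response is linear in the kick strength", {
  sys <- toy_geometry("H2")
  ints <- compute_integrals(sys)
  res <- run_rhf(ints)
  resp <- vapply(c(1e-4, 2e-4), function(k) {
    P1 <- apply_kick(res$density, ints, kick_field(k, "z"))
    tr <- propagate(P1, ints, dt = 0.25, n_steps = 3)
    tr$total_dipole[1, 3] - (-sum(Re(res$density) * ints$D$z))
  }, numeric(1))
  expect_equal(resp[2] / resp[1], 2, tolerance = 0.01)
})

test_that("an unperturbed ground state is stationary", {
  sys <- toy_geometry("H2O")
  ints <- compute_integrals(sys)
  res <- run_rhf(ints, conv_energy = 1e-11, conv_density = 1e-9)
  tr <- propagate(res$density, ints, dt = 0.25, n_steps = 500)
  rng <- apply(tr$total_dipole, 2, function(v) diff(range(v)))
  expect_lt(max(rng), 1e-8)
  expect_lt(trace_drift(tr), 1e-10)
})

test_that("energy is conserved after the kick", {
  sys <- toy_geometry("H2O")
  ints <- compute_integrals(sys)
  res <- run_rhf(ints)
  P1 <- apply_kick(res$density, ints, kick_field(2e-4, "y"))
  tr <- propagate(P1, ints, dt = 0.25, n_steps = 500)
  expect_lt(max(abs(tr$energy - tr$energy[1])), 1e-6)
})

test_that("per-basis dipole contributions sum exactly to the total dipole", {
  sys <- toy_geometry("H2O")
  ints <- compute_integrals(sys)
  res <- run_rhf(ints)
  P1 <- apply_kick(res$density, ints, kick_field(2e-4, "x"))
  tr <- propagate(P1, ints, dt = 0.25, n_steps = 50)
  for (d in 1:3) {
    expect_lt(max(abs(rowSums(tr$per_basis[[d]]) - tr$total_dipole[, d])),
              1e-10)
  }
})

test_that("trace drift stays small and shrinks with the time step", {
  sys <- toy_geometry("H2")
  ints <- compute_integrals(sys)
  res <- run_rhf(ints)
  P1 <- apply_kick(res$density, ints, kick_field(2e-4, "z"))
  tr1 <- propagate(P1, ints, dt = 0.25, n_steps = 500)
  expect_lt(trace_drift(tr1), 1e-7)
  tr2 <- propagate(P1, ints, dt = 0.125, n_steps = 1000)
  expect_lte(trace_drift(tr2), trace_drift(tr1) + 1e-12)
})

test_that("schedule metadata records the physical duration", {
  sys <- toy_geometry("H2")
  ints <- compute_integrals(sys)
  res <- run_rhf(ints)
  tr <- propagate(res$density, ints, dt = 0.25, n_steps = 20)
  expect_equal(tr$duration_fs, 20 * 0.25 * 0.02418884254, tolerance = 1e-12)
  expect_equal(tr$times[length(tr$times)], 20 * 0.25)
})

test_that("RT peak energies agree with linear-response TDHF on H2 and HeH+", {
  grid <- seq(10, 45, by = 0.01) / 27.211386245
  for (name in c("H2", "HeH+")) {
    sys <- toy_geometry(name)
    ints <- compute_integrals(sys)
    scf <- run_rhf(ints)
    om_lr <- oracle_lr_tdhf(sys)
    out <- rt_spectrum(ints, scf, n_steps = 1600, energies = grid)
    sp <- out$spectrum
    pk <- sp$energy[which.max(sp$isotropic)]
    # dominant dipole-allowed excitation within the damping-set resolution
    expect_lt(min(abs(om_lr - pk)), 0.0075,
              label = sprintf("%s: RT peak %.4f vs LR %s", name, pk,
                              paste(round(om_lr, 4), collapse = "/")))
    expect_gt(max(sp$isotropic), 0)   # absorption positive at resonance
  }
})
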