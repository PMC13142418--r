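# Bond detection and quantum-region carving.

test_that("ethane has exactly one C-C single bond and six C-H bonds", {
  b <- detect_bonds(toy_geometry("ethane"))
  expect_equal(sum(b$character == "single_CC"), 1L)
  expect_equal(sum(b$character == "other"), 6L)
  cc <- b[b$character == "single_CC", ]
  expect_equal(cc$length, 1.536, tolerance = 1e-6)
})

test_that("aromatic carbon-carbon contacts are never classified as single bonds", {
  b <- detect_bonds(toy_geometry("benzene"))
  ring <- b[b$i <= 6 & b$j <= 6, ]
  expect_gt(nrow(ring), 0)
  expect_true(all(ring$character == "other"))
})

test_that("single atoms yield an empty bond list and clashes are rejected", {
  expect_equal(nrow(detect_bonds(toy_geometry("He"))), 0L)
  clash <- data.frame(element = c("H", "H"), x = c(0, 0.3), y = 0, z = 0)
  expect_error(detect_bonds(clash), "clash")
})

test_that("cutoff zero carves exactly the ligand with no caps", {
  bundle <- make_mini_protein(seed = 1)
  sys <- carve(bundle$atoms, bundle$ligand_indices, environment_spec(cutoff = 0))
  expect_equal(sort(sys$atoms$serial),
               sort(bundle$atoms$serial[bundle$ligand_indices]))
  expect_false(any(sys$atoms$is_cap))
  expect_true(is.na(sys$total_charge))
})

test_that("carving matches the brute-force ground truth on seeded fixtures", {
  for (seed in 1:6) {
    bundle <- make_mini_protein(seed = seed)
    for (co in c(3, 5)) {
      sys <- carve(bundle$atoms, bundle$ligand_indices,
                   environment_spec(cutoff = co))
      truth <- bundle$expected[[paste0("cutoff_", co)]]
      expect_equal(sort(sys$atoms$serial[!sys$atoms$is_cap]),
                   sort(truth$inside_serial),
                   info = sprintf("seed %d cutoff %g", seed, co))
      caps <- as.matrix(sys$atoms[sys$atoms$is_cap, c("x", "y", "z")])
      if (is.null(truth$caps)) {
        expect_equal(nrow(caps), 0L)
      } else {
        expect_equal(nrow(caps), nrow(truth$caps))
        expect_lt(max(abs(caps - truth$caps)), 1e-9)
      }
    }
  }
})

test_that("only carbon-carbon single bonds are ever cut", {
  for (seed in c(1, 4, 7)) {
    bundle <- make_mini_protein(seed = seed)
    sys <- carve(bundle$atoms, bundle$ligand_indices, environment_spec(cutoff = 3))
    kept <- sys$atoms$serial[!sys$atoms$is_cap]
    inside <- bundle$atoms$serial %in% kept
    b <- bundle$expected$bonds
    crossing <- xor(inside[b$i], inside[b$j])
    expect_true(all(b$character[crossing] == "single_CC"))
  }
})

test_that("cap hydrogens lie on the original bond vector at the cap length", {
  bundle <- make_mini_protein(seed = 2)
  spec <- environment_spec(cutoff = 3)
  sys <- carve(bundle$atoms, bundle$ligand_indices, spec)
  caps <- sys$atoms[sys$atoms$is_cap, ]
  expect_gt(nrow(caps), 0)
  kept <- sys$atoms$serial[!sys$atoms$is_cap]
  inside <- bundle$atoms$serial %in% kept
  b <- bundle$expected$bonds
  crossing <- which(xor(inside[b$i], inside[b$j]))
  for (ci in seq_len(nrow(caps))) {
    # find the crossing bond this cap belongs to
    best <- Inf
    for (bi in crossing) {
      a_in <- if (inside[b$i[bi]]) b$i[bi] else b$j[bi]
      a_out <- if (inside[b$i[bi]]) b$j[bi] else b$i[bi]
      r_in <- unlist(bundle$atoms[a_in, c("x", "y", "z")])
      r_out <- unlist(bundle$atoms[a_out, c("x", "y", "z")])
      u <- (r_out - r_in) / sqrt(sum((r_out - r_in)^2))
      pred <- r_in + spec$cap_bond_length * u
      best <- min(best, max(abs(pred - unlist(caps[ci, c("x", "y", "z")]))))
    }
    expect_lt(best, 1e-6)
  }
})

test_that("carving is independent of input atom order", {
  bundle <- make_mini_protein(seed = 5)
  sys1 <- carve(bundle$atoms, bundle$ligand_indices, environment_spec(cutoff = 3))
  perm <- c(seq(2, nrow(bundle$atoms), by = 2), seq(1, nrow(bundle$atoms), by = 2))
  shuffled <- bundle$atoms[perm, ]
  lig2 <- which(shuffled$resname == "LIG")
  sys2 <- carve(shuffled, lig2, environment_spec(cutoff = 3))
  expect_equal(sort(sys1$atoms$serial[!sys1$atoms$is_cap]),
               sort(sys2$atoms$serial[!sys2$atoms$is_cap]))
  c1 <- as.matrix(sys1$atoms[sys1$atoms$is_cap, c("x", "y", "z")])
  c2 <- as.matrix(sys2$atoms[sys2$atoms$is_cap, c("x", "y", "z")])
  expect_equal(c1, c2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("growth that consumes the whole structure warns and returns it uncut", {
  benz <- toy_geometry("benzene")$atoms
  expect_warning(sys <- carve(benz, 1L, environment_spec(cutoff = 0)),
                 "entire structure")
  expect_equal(nrow(sys$atoms), nrow(benz))
  expect_false(any(sys$atoms$is_cap))
})

test_that("ligand indices outside the structure are rejected", {
  benz <- toy_geometry("benzene")$atoms
  expect_error(carve(benz, 99L, environment_spec(cutoff = 0)), "outside")
  expect_error(carve(benz, integer(0)), "empty")
})
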