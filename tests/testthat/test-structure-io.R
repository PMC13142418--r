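# Structure reading/writing and ligand selection.

test_that("XYZ round trip preserves elements and positions", {
  h2o <- toy_geometry("H2O")
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(h2o, f, comment = "water fixture")
  back <- read_xyz(f)
  expect_equal(back$element, h2o$atoms$element)
  expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
                      as.matrix(h2o$atoms[, c("x", "y", "z")]))), 1e-4)
})

test_that("XYZ header mismatch and malformed input raise errors", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "broken", "H 0 0 0", "H 0 0 0.74"), f)
  expect_error(read_xyz(f), "declares 3 atoms")
  writeLines(c("nope", "x"), f)
  expect_error(read_xyz(f), "malformed")
})

test_that("mini-protein PDB round trip matches the generator ground truth", {
  bundle <- make_mini_protein(seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bundle$pdb, f)
  atoms <- read_pdb(f)
  expect_equal(nrow(atoms), nrow(bundle$atoms))
  expect_equal(atoms$element, bundle$atoms$element)
  # PDB stores three decimals
  expect_lt(max(abs(as.matrix(atoms[, c("x", "y", "z")]) -
                      as.matrix(bundle$atoms[, c("x", "y", "z")]))), 1.5e-3)
  expect_equal(atoms$resname, bundle$atoms$resname)
})

test_that("a single HETATM iron record parses to one Fe atom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(paste0(
    "HETATM    1 FE    FE A 101      10.000  11.000  12.000  1.00  0.00",
    "          FE"), f)
  atoms <- suppressWarnings(read_pdb(f))
  expect_equal(nrow(atoms), 1L)
  expect_equal(atoms$element, "Fe")
  expect_equal(c(atoms$x, atoms$y, atoms$z), c(10, 11, 12))
})

test_that("files without coordinate records are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "REMARK    EMPTY", "END"), f)
  expect_error(suppressWarnings(read_pdb(f)))
})

test_that("alternate locations keep the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  CA %sALA A   1    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            1L, "A", 0, 0, 0, 0.3, 0),
    sprintf("ATOM  %5d  CA %sALA A   1    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            2L, "B", 1, 0, 0, 0.7, 0),
    "END"), f)
  atoms <- suppressWarnings(read_pdb(f))
  expect_equal(nrow(atoms), 1L)
  expect_equal(atoms$x, 1)   # the B conformer has the higher occupancy
})

test_that("heavy-atom-only structures trigger a protonation warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  sys <- toy_geometry("H2O")
  heavy <- sys$atoms[sys$atoms$element != "H", ]
  write_pdb(heavy, f)
  expect_warning(read_pdb(f), "hydrogen")
})

test_that("carved systems written to PDB keep cap hydrogens identifiable", {
  bundle <- make_mini_protein(seed = 3)
  carved <- carve(bundle$atoms, bundle$ligand_indices,
                  environment_spec(cutoff = 3))
  expect_gt(sum(carved$atoms$is_cap), 0)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(carved, f)
  back <- read_pdb(f)
  expect_equal(sum(back$is_cap), sum(carved$atoms$is_cap))
  expect_true(all(back$resname[back$is_cap] == "CAP"))
})

test_that("ligand selection returns the generator's ligand set and is order-invariant", {
  bundle <- make_mini_protein(seed = 2)
  idx <- select_ligand(bundle$atoms, "LIG")
  expect_equal(idx, bundle$ligand_indices)
  # reorder atoms; selection must pick the same serials
  perm <- rev(seq_len(nrow(bundle$atoms)))
  shuffled <- bundle$atoms[perm, ]
  idx2 <- select_ligand(shuffled, "LIG")
  expect_equal(sort(shuffled$serial[idx2]),
               sort(bundle$atoms$serial[bundle$ligand_indices]))
})

test_that("ligand selection errors on absent residues and covers the identity case", {
  bundle <- make_mini_protein(seed = 1)
  expect_error(select_ligand(bundle$atoms, "XYZ"), "no atoms")
  lig_only <- bundle$atoms[bundle$ligand_indices, ]
  expect_equal(select_ligand(lig_only, "LIG"), seq_len(nrow(lig_only)))
})

test_that("hydrogens bonded to the ligand are included in the selection", {
  # a ligand residue whose hydrogens are mislabelled with a different name
  at <- toy_geometry("CH4")$atoms
  at$resname <- c("LIG", rep("HOH", 4))
  idx <- select_ligand(at, "LIG")
  expect_equal(idx, 1:5)   # the four hydrogens ride along
})
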