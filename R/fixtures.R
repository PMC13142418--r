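# Synthetic fixtures: toy molecular geometries with known properties and a
# mini-protein generator whose carve/cap/bond ground truth is computed by an
# independent brute-force pass at generation time.
#
# The tryptophan, glycine and FAD geometries are idealized gas-phase
# conformers built from standard bond lengths/angles and force-field
# relaxation of the covalent topology (synthetic templates, not any specific
# crystal structure); the remaining geometries use textbook bond parameters.

.toy_data <- local({
  sq3 <- sqrt(3)
  d_ch4 <- 1.089 / sq3
  # staggered ethane: HCC angle 111.2 deg, C-H 1.091, C-C 1.536
  eth_r <- 1.091 * sin(111.2 * pi / 180)
  eth_z <- 1.091 * cos(111.2 * pi / 180)
  ang <- function(deg) deg * pi / 180
  benz_c <- t(vapply(0:5, function(k) 1.39 * c(cos(ang(60 * k)), sin(ang(60 * k)), 0),
                     numeric(3)))
  benz_h <- t(vapply(0:5, function(k) 2.48 * c(cos(ang(60 * k)), sin(ang(60 * k)), 0),
                     numeric(3)))
  list(
    H2 = list(element = c("H", "H"),
              xyz = matrix(c(0, 0, 0, 0, 0, 1.4 / ANGSTROM_TO_BOHR),
                           ncol = 3, byrow = TRUE),
              charge = 0L),
    He = list(element = "He", xyz = matrix(0, 1, 3), charge = 0L),
    `HeH+` = list(element = c("He", "H"),
                  xyz = matrix(c(0, 0, 0, 0, 0, 0.7743), ncol = 3, byrow = TRUE),
                  charge = 1L),
    H2O = list(element = c("O", "H", "H"),
               xyz = matrix(c(0, 0, 0.117790,
                              0, 0.755453, -0.471161,
                              0, -0.755453, -0.471161), ncol = 3, byrow = TRUE),
               charge = 0L),
    CH4 = list(element = c("C", rep("H", 4)),
               xyz = matrix(c(0, 0, 0,
                              d_ch4, d_ch4, d_ch4,
                              d_ch4, -d_ch4, -d_ch4,
                              -d_ch4, d_ch4, -d_ch4,
                              -d_ch4, -d_ch4, d_ch4), ncol = 3, byrow = TRUE),
               charge = 0L),
    ethane = list(
      element = c("C", "C", rep("H", 6)),
      xyz = rbind(c(0, 0, 0), c(0, 0, 1.536),
                  t(vapply(c(0, 120, 240), function(a)
                    c(eth_r * cos(ang(a)), eth_r * sin(ang(a)), eth_z),
                    numeric(3))),
                  t(vapply(c(60, 180, 300), function(a)
                    c(eth_r * cos(ang(a)), eth_r * sin(ang(a)), 1.536 - eth_z),
                    numeric(3)))),
      charge = 0L),
    benzene = list(element = c(rep("C", 6), rep("H", 6)),
                   xyz = rbind(benz_c, benz_h), charge = 0L),
    glycine = list(
      element = c("C", "C", "O", "O", "N", "H", "H", "H", "H", "H"),
      xyz = matrix(c(
        -0.568211, -0.499362, -0.204468,
        0.920400, -0.258474, -0.413061,
        1.707979, -1.025127, -0.944562,
        1.325657, 0.971485, -0.020829,
        -1.058495, 0.172316, 1.011136,
        -1.098363, -0.120956, -1.083586,
        -0.740442, -1.574972, -0.108514,
        2.286682, 0.967542, -0.211661,
        -2.073571, 0.236500, 0.972712,
        -0.701636, 1.131047, 1.002833), ncol = 3, byrow = TRUE),
      charge = 0L),
    tryptophan = list(
      element = c("C", "C", "C", "C", "C", "C", "C", "C", "N", "C", "C", "C",
                  "O", "O", "N", "H", "H", "H", "H", "H", "H", "H", "H", "H",
                  "H", "H", "H"),
      xyz = matrix(c(
        2.605705, 2.077284, -0.496569,
        3.603196, 1.184164, -0.879502,
        3.431192, -0.194767, -0.728750,
        2.222740, -0.642156, -0.181314,
        1.203148, 0.225896, 0.210627,
        1.403153, 1.612599, 0.048791,
        0.126591, -0.575003, 0.713576,
        0.531461, -1.891657, 0.618381,
        1.788325, -1.920310, 0.080086,
        -1.190433, -0.084277, 1.241442,
        -2.202743, 0.212012, 0.124771,
        -2.900217, -1.066691, -0.364192,
        -2.650794, -2.227349, -0.085262,
        -3.907642, -0.789157, -1.232028,
        -3.236642, 1.168849, 0.603641,
        2.761557, 3.146111, -0.619732,
        4.531432, 1.563866, -1.300348,
        4.211000, -0.888121, -1.025993,
        0.635083, 2.319376, 0.346930,
        0.022340, -2.810386, 0.882006,
        2.323672, -2.757334, -0.103073,
        -0.993319, 0.828935, 1.819425,
        -1.598796, -0.811823, 1.954992,
        -1.701221, 0.654806, -0.744605,
        -4.268394, -1.675673, -1.442749,
        -3.937827, 1.250599, -0.137687,
        -2.812566, 2.090206, 0.697136), ncol = 3, byrow = TRUE),
      charge = 0L),
    FAD_oxidized = list(
      element = c("C", "C", "C", "C", "N", "C", "C", "O", "N", "C", "O", "N",
                  "C", "C", "O", "C", "O", "C", "O", "C", "O", "P", "O", "O",
                  "O", "P", "O", "O", "O", "C", "C", "O", "C", "N", "C", "N",
                  "C", "C", "N", "N", "C", "N", "C", "C", "O", "C", "O", "C",
                  "N", "C", "C", "C", "C", "H", "H", "H", "H", "H", "H", "H",
                  "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H",
                  "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H"),
      xyz = matrix(c(
        -4.672426, 2.294340, 5.198986,
        -4.629710, 1.622511, 3.856190,
        -5.791615, 1.573463, 3.066954,
        -5.802705, 0.991279, 1.804781,
        -6.933330, 1.001749, 1.070268,
        -6.829615, 0.461552, -0.175600,
        -8.018493, 0.488759, -1.049552,
        -9.111285, 0.916852, -0.688978,
        -7.842538, -0.019203, -2.313377,
        -6.715104, -0.616351, -2.815827,
        -6.769245, -1.110811, -3.940599,
        -5.620999, -0.645512, -1.982760,
        -4.328688, -1.174911, -2.455742,
        -3.263454, -0.080237, -2.676732,
        -3.725594, 0.831946, -3.693438,
        -1.889758, -0.678206, -3.070101,
        -1.578601, -1.817577, -2.261209,
        -0.794604, 0.408008, -2.977163,
        -1.115560, 1.526164, -3.828531,
        0.591142, -0.150238, -3.338366,
        1.692521, 0.726818, -3.165045,
        1.716246, 1.906475, -2.061109,
        3.125651, 2.478222, -2.109181,
        0.541399, 2.816861, -2.323025,
        1.622385, 1.114872, -0.695345,
        0.672936, 0.294392, 0.262598,
        0.039583, -0.876697, -0.455328,
        -0.174793, 1.197597, 1.120438,
        1.845413, -0.332888, 1.215525,
        2.322173, 0.429743, 2.312955,
        3.779588, 0.887374, 2.165496,
        4.669474, -0.260574, 2.086247,
        5.370532, -0.177834, 0.818517,
        5.551099, -1.520855, 0.307572,
        4.585374, -2.489731, 0.188186,
        5.070979, -3.616753, -0.297559,
        6.406832, -3.354579, -0.508428,
        7.447186, -4.140996, -1.031783,
        7.258761, -5.453213, -1.468715,
        8.678524, -3.595297, -1.156752,
        8.847073, -2.319908, -0.740170,
        7.940187, -1.479770, -0.207483,
        6.729305, -2.059972, -0.135558,
        4.545456, 0.735109, -0.083396,
        5.275298, 1.394459, -1.120485,
        4.049655, 1.745562, 0.937442,
        5.131323, 2.666297, 1.220164,
        -5.672877, -0.113300, -0.673520,
        -4.570616, -0.171103, 0.100002,
        -4.612719, 0.410167, 1.312680,
        -3.464826, 0.455634, 2.087901,
        -3.449338, 1.048906, 3.359716,
        -2.143362, 1.113586, 4.104015,
        -5.645841, 2.760990, 5.383976,
        -3.916052, 3.083627, 5.256490,
        -4.498175, 1.562501, 5.993996,
        -6.714508, 2.020042, 3.429796,
        -8.643297, -0.015758, -2.924645,
        -4.493929, -1.701536, -3.403066,
        -3.996509, -1.925334, -1.728856,
        -3.138518, 0.509482, -1.763981,
        -2.941249, 1.396847, -3.890241,
        -1.954227, -1.021496, -4.110209,
        -1.028494, -1.498295, -1.485955,
        -0.805560, 0.797534, -1.958555,
        -0.534255, 2.245617, -3.443823,
        0.590418, -0.416764, -4.401573,
        0.823543, -1.066425, -2.790568,
        2.245065, -0.221719, 3.190157,
        1.694622, 1.304345, 2.504435,
        4.059803, 1.427159, 3.077814,
        6.363579, 0.243763, 1.015013,
        3.551866, -2.313695, 0.468274,
        7.911912, -5.672999, -2.207818,
        6.274677, -5.627617, -1.657826,
        9.849680, -1.918050, -0.850833,
        3.740681, 0.159050, -0.542998,
        4.559700, 1.864094, -1.646386,
        3.206490, 2.363009, 0.627307,
        5.414168, 2.952734, 0.324702,
        -2.541203, 0.048616, 1.668718,
        -2.282974, 0.850731, 5.157250,
        -1.722035, 2.121237, 4.034490,
        -1.413614, 0.406134, 3.695809), ncol = 3, byrow = TRUE),
      charge = -2L)
  )
})

#' Toy molecular geometries with known properties
#'
#' Fixed idealized geometries in Angstrom.  `FAD_oxidized` is the oxidized
#' flavin adenine dinucleotide dianion (composition C27H31N9O15P2, total
#' charge -2, hence 408 electrons); `HeH+` carries charge +1.
#'
#' @param name one of `r paste0('"', paste(names(.toy_data), collapse = '", "'), '"')`.
#' @return a [molecular_system()].
#' @export
toy_geometry <- function(name) {
  if (!name %in% names(.toy_data)) {
    stop("unknown toy geometry '", name, "'; available: ",
         paste(names(.toy_data), collapse = ", "))
  }
  g <- .toy_data[[name]]
  atoms <- data.frame(element = g$element, x = g$xyz[, 1], y = g$xyz[, 2],
                      z = g$xyz[, 3], stringsAsFactors = FALSE)
  molecular_system(atoms, total_charge = g$charge, label = name)
}

# minimal deterministic Lehmer generator, independent of R's RNG state
.lehmer <- function(seed) {
  state <- (abs(as.numeric(seed)) %% 2147483646) + 1
  function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
}

.rot_matrix <- function(u1, u2, u3) {
  # uniform random rotation (Shoemake quaternion construction)
  q <- c(sqrt(1 - u1) * sin(2 * pi * u2), sqrt(1 - u1) * cos(2 * pi * u2),
         sqrt(u1) * sin(2 * pi * u3), sqrt(u1) * cos(2 * pi * u3))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# propane-like fake ligand and an alanine-like residue template (Angstrom)
.mini_ligand <- function() {
  data.frame(
    element = c("C", "C", "C", "H", "H", "H", "H", "H", "H", "H", "H"),
    x = c(0, 1.530, 2.043, -0.363, -0.363, -0.363, 1.893, 1.893, 1.680, 1.680, 3.070),
    y = c(0, 0, 1.442, -1.027, 0.513, 0.513, -0.513, -0.513, 1.955, 1.955, 1.805),
    z = c(0, 0, 0, 0, 0.889, -0.889, 0.889, -0.889, -0.889, 0.889, 0),
    stringsAsFactors = FALSE)
}

.mini_residue <- function() {
  data.frame(
    element = c("N", "H", "C", "H", "C", "H", "H", "H", "C", "O"),
    x = c(0, -0.58, 1.458, 1.821, 1.983, 2.873, 1.383, 2.083, 1.938, 2.336),
    y = c(0, -0.82, 0, 0.50, 0.72, 1.22, 1.57, 0.32, 1.063, 2.157),
    z = c(0, 0, 0, 0.87, -1.25, -1.45, -1.55, -2.25, 0.975, 1.373),
    stringsAsFactors = FALSE)
}

# independent brute-force bond/carve/cap oracle used for the generator's
# ground truth (plain set iteration over explicitly recomputed distances)
.bonds_bruteforce <- function(atoms, scale = 1.3, cc_min = 1.45) {
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rc <- covalent_radius(atoms$element)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= scale * (rc[i] + rc[j])) {
      cc <- atoms$element[i] == "C" && atoms$element[j] == "C" && d >= cc_min
      out <- rbind(out, data.frame(i = i, j = j, length = d,
                                   character = if (cc) "single_CC" else "other",
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

.carve_bruteforce <- function(atoms, ligand_idx, cutoff,
                              scale = 1.3, cc_min = 1.45, cap_len = 1.09) {
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  bl <- .bonds_bruteforce(atoms, scale, cc_min)
  bonded <- matrix(FALSE, n, n)
  single_cc <- matrix(FALSE, n, n)
  for (r in seq_len(NROW(bl))) {
    i <- bl$i[r]; j <- bl$j[r]
    bonded[i, j] <- bonded[j, i] <- TRUE
    if (bl$character[r] == "single_CC") {
      single_cc[i, j] <- single_cc[j, i] <- TRUE
    }
  }
  inside <- rep(FALSE, n)
  inside[ligand_idx] <- TRUE
  if (cutoff > 0) {
    for (a in seq_len(n)) {
      if (inside[a]) next
      for (l in ligand_idx) {
        if (sqrt(sum((xyz[a, ] - xyz[l, ])^2)) <= cutoff) {
          inside[a] <- TRUE
          break
        }
      }
    }
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (bonded[i, j] && inside[i] && !inside[j] && !single_cc[i, j]) {
        inside[j] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  caps <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (bonded[i, j] && inside[i] && !inside[j]) {
      v <- xyz[j, ] - xyz[i, ]
      v <- v / sqrt(sum(v^2))
      caps <- rbind(caps, c(xyz[i, ] + cap_len * v, xyz[i, ], xyz[j, ]))
    }
  }
  if (!is.null(caps)) {
    ord <- do.call(order, as.data.frame(caps[, 4:9, drop = FALSE]))
    caps <- caps[ord, 1:3, drop = FALSE]
  }
  list(inside = which(inside), caps = caps)
}

#' Generate a synthetic mini-protein fixture with carve ground truth
#'
#' Places a small fake ligand (residue name `LIG`) surrounded by
#' alanine-like residues at controlled minimum distances, and records, for
#' cutoffs 0/3/5 Angstrom, the exact post-growth atom set and cap-hydrogen
#' positions computed by an independent brute-force pass at generation time.
#' Deterministic for a given seed.
#'
#' @param seed integer seed for the internal (R-RNG-independent) generator.
#' @param n_residues number of residues placed around the ligand.
#' @param offsets minimum distance (Angstrom) of each residue to the ligand;
#'   recycled to `n_residues`.
#' @return list of class `fixture_bundle` with `atoms`, `pdb` (text lines),
#'   `ligand_indices`, `expected` (per-cutoff inside sets and cap positions,
#'   plus the bond list) and `seed`.
#' @export
make_mini_protein <- function(seed = 1, n_residues = 2, offsets = c(2.5, 6.0)) {
  stopifnot(n_residues >= 1)
  offsets <- rep_len(offsets, n_residues)
  rng <- .lehmer(seed)
  lig <- .mini_ligand()
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  lig_xyz <- sweep(lig_xyz, 2, colMeans(lig_xyz))   # center the ligand
  res_t <- .mini_residue()
  res_xyz0 <- as.matrix(res_t[, c("x", "y", "z")])
  res_xyz0 <- sweep(res_xyz0, 2, colMeans(res_xyz0))
  placed <- list()
  for (r in seq_len(n_residues)) {
    ok <- FALSE
    for (attempt in 1:50) {
      R <- .rot_matrix(rng(), rng(), rng())
      # spread directions: golden-angle azimuth plus jitter
      az <- 2.399963 * (r - 1) + 0.5 * (rng() - 0.5)
      polar <- acos(2 * rng() - 1) * 0.3 + pi / 2 * 0.7
      u <- c(cos(az) * sin(polar), sin(az) * sin(polar), cos(polar))
      pos <- res_xyz0 %*% t(R)
      pos <- sweep(pos, 2, u * (offsets[r] + 6), `+`)
      # slide along u until the minimum distance to the ligand equals the offset
      for (it in 1:100) {
        d2 <- pmax(outer(rowSums(pos^2), rowSums(lig_xyz^2), `+`) -
                     2 * pos %*% t(lig_xyz), 0)
        dmin <- min(sqrt(d2))
        if (abs(dmin - offsets[r]) < 1e-9) break
        pos <- sweep(pos, 2, (dmin - offsets[r]) * u, `-`)
      }
      # no clashes with the ligand or previously placed residues
      others <- rbind(lig_xyz, do.call(rbind, lapply(placed, `[[`, "xyz")))
      dall <- sqrt(pmax(outer(rowSums(pos^2), rowSums(others^2), `+`) -
                          2 * pos %*% t(others), 0))
      if (min(dall) > 1.7) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place residue ", r, " without clashes")
    placed[[r]] <- list(xyz = pos)
  }
  atoms <- data.frame(
    element = lig$element, x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
    resname = "LIG", resseq = 0L, chain = "L", stringsAsFactors = FALSE)
  for (r in seq_len(n_residues)) {
    pos <- placed[[r]]$xyz
    atoms <- rbind(atoms, data.frame(
      element = res_t$element, x = pos[, 1], y = pos[, 2], z = pos[, 3],
      resname = "ALA", resseq = r, chain = "A", stringsAsFactors = FALSE))
  }
  atoms$serial <- seq_len(nrow(atoms))
  atoms <- .as_atom_frame(atoms)
  ligand_idx <- which(atoms$resname == "LIG")
  expected <- list(bonds = .bonds_bruteforce(atoms))
  for (co in c(0, 3, 5)) {
    bf <- .carve_bruteforce(atoms, ligand_idx, co)
    expected[[paste0("cutoff_", co)]] <- list(
      inside_serial = atoms$serial[bf$inside], caps = bf$caps)
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  write_pdb(atoms, tmp)
  structure(list(atoms = atoms, pdb = readLines(tmp),
                 ligand_indices = ligand_idx, expected = expected,
                 seed = seed),
            class = "fixture_bundle")
}
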