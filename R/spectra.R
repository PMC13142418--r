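# From dipole traces to absorption spectra: baseline correction, damped
# Fourier transform (Lorentzian lines), isotropic assembly, peak finding with
# parabolic refinement, constant-shift calibration and per-atom maps.

.default_energy_grid <- function() {
  seq(1, 10, by = 0.0025) / HARTREE_TO_EV   # 1-10 eV, 2.5 meV resolution
}

#' Baseline-correct a dipole time series
#'
#' Subtracts, per Cartesian component, the mean over the trailing
#' `tail_fraction` of the series (the last 9,000 of 10,000 steps at
#' defaults), removing the static offset left after the kick.
#'
#' @param x numeric vector or matrix (time along rows).
#' @param tail_fraction fraction of the series (from the end) used for the
#'   mean.
#' @return corrected vector/matrix of the same shape.
#' @export
baseline_correct <- function(x, tail_fraction = 0.9) {
  v <- as.matrix(x)
  n <- nrow(v)
  if (n < 10) stop("series too short for baseline correction")
  ntail <- max(1, round(tail_fraction * n))
  idx <- seq.int(n - ntail + 1, n)
  mu <- colMeans(v[idx, , drop = FALSE])
  out <- sweep(v, 2, mu)
  if (is.null(dim(x))) drop(out) else out
}

#' Damped Fourier transform of a time series
#'
#' `F(w) = sum_k dt exp(i w t_k) exp(-gamma t_k) x(t_k)` on an energy grid in
#' Hartree (w = E in atomic units).  The exponential damping produces
#' Lorentzian lines of half-width `gamma`.
#'
#' @param x numeric vector or matrix (time along rows), typically
#'   baseline-corrected.
#' @param times sample times in atomic units (uniform spacing).
#' @param attenuation damping rate gamma in atomic units (> 0).
#' @param energies energy grid in Hartree; defaults to 1-10 eV at 2.5 meV.
#' @return list with `energies` and complex `transform` (grid x columns).
#' @export
damped_ft <- function(x, times, attenuation = 0.015,
                      energies = .default_energy_grid()) {
  if (attenuation <= 0) stop("attenuation must be positive")
  v <- as.matrix(x)
  stopifnot(nrow(v) == length(times))
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  damped <- v * exp(-attenuation * times)
  out <- matrix(0i, length(energies), ncol(v))
  chunk <- 256L
  for (s in seq(1, length(energies), by = chunk)) {
    ee <- s:min(s + chunk - 1L, length(energies))
    ph <- exp(1i * outer(energies[ee], times))
    out[ee, ] <- ph %*% damped * dt
  }
  list(energies = energies, transform = out)
}

.new_spectrum <- function(energies, strength, isotropic, attenuation,
                          shift = 0, label = "") {
  structure(list(wavelength = HC_NM_HARTREE / energies, energy = energies,
                 strength = strength, isotropic = isotropic,
                 attenuation = attenuation, shift_applied = shift,
                 label = label),
            class = "absorption_spectrum")
}

#' Assemble an absorption spectrum from three kick-direction traces
#'
#' For each kick direction the diagonal dipole response is baseline-corrected
#' and Fourier-transformed; the per-direction absorption strength is
#' `E * Im F(E) / kappa` and the isotropic spectrum is the mean of the three
#' diagonal responses.  Wavelengths follow `lambda[nm] = 45.5634 / E[Ha]`.
#'
#' @param traces named list with elements `x`, `y`, `z`: [propagate()] traces
#'   kicked along the respective axes with identical schedules.
#' @param kick_strength field impulse kappa used for the kicks (au).
#' @param attenuation damping rate gamma (au).
#' @param tail_fraction baseline-correction tail fraction.
#' @param energies energy grid in Hartree.
#' @param label free-text label.
#' @return object of class `absorption_spectrum` with `wavelength` (nm),
#'   `energy` (Ha), `strength` (grid x 3 matrix), `isotropic`, `attenuation`,
#'   `shift_applied`.
#' @export
absorption <- function(traces, kick_strength, attenuation = 0.015,
                       tail_fraction = 0.9, energies = .default_energy_grid(),
                       label = "") {
  stopifnot(all(c("x", "y", "z") %in% names(traces)))
  sched <- lapply(traces[c("x", "y", "z")],
                  function(tr) c(tr$dt, tr$n_steps))
  if (length(unique(sched)) != 1) stop("mismatched propagation schedules")
  strength <- matrix(0, length(energies), 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  for (d in 1:3) {
    tr <- traces[[c("x", "y", "z")[d]]]
    mu <- baseline_correct(tr$total_dipole[, d], tail_fraction)
    ft <- damped_ft(mu, tr$times, attenuation, energies)
    strength[, d] <- energies * Im(ft$transform[, 1]) / kick_strength
  }
  .new_spectrum(energies, strength, rowMeans(strength), attenuation,
                label = label)
}

#' @export
print.absorption_spectrum <- function(x, ...) {
  pk <- tryCatch(find_peaks(x, window = range(x$wavelength)),
                 error = function(e) NULL)
  cat(sprintf("absorption_spectrum '%s': %d grid points, gamma = %g au, shift %g nm\n",
              x$label, length(x$energy), x$attenuation, x$shift_applied))
  if (!is.null(pk) && nrow(pk) > 0) {
    cat("  main peaks (nm):",
        paste(sprintf("%.1f", utils::head(pk$wavelength[order(-pk$height)], 4)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Locate absorption peaks in a wavelength window
#'
#' Strict local maxima of the isotropic strength above a height floor
#' (default 1% of the window maximum), refined by three-point parabolic
#' interpolation on the energy grid.
#'
#' @param spectrum an [absorption()] result (or any list with `energy`,
#'   `isotropic`; a `wavelength` field is honoured if shifted).
#' @param window two-element wavelength window in nm.
#' @param floor_frac height floor as a fraction of the window maximum.
#' @return data frame with `wavelength` (nm) and `height`, sorted by
#'   wavelength.
#' @export
find_peaks <- function(spectrum, window, floor_frac = 0.01) {
  wl <- if (!is.null(spectrum$wavelength)) spectrum$wavelength else
    HC_NM_HARTREE / spectrum$energy
  shift <- if (!is.null(spectrum$shift_applied)) spectrum$shift_applied else 0
  y <- spectrum$isotropic
  sel <- which(wl >= min(window) & wl <= max(window))
  if (length(sel) < 3) stop("empty or too narrow peak-search window")
  sel <- sel[order(spectrum$energy[sel])]
  e <- spectrum$energy[sel]; ys <- y[sel]
  floorh <- floor_frac * max(ys)
  n <- length(ys)
  out <- list()
  for (k in 2:(n - 1)) {
    if (ys[k] > ys[k - 1] && ys[k] > ys[k + 1] && ys[k] >= floorh) {
      # parabolic refinement on the (uniform) energy grid
      d1 <- (ys[k + 1] - ys[k - 1]) / 2
      d2 <- ys[k + 1] - 2 * ys[k] + ys[k - 1]
      off <- if (d2 < 0) -d1 / d2 else 0
      off <- max(-0.5, min(0.5, off))
      e_pk <- e[k] + off * (e[k + 1] - e[k])
      h_pk <- if (d2 < 0) ys[k] - d1^2 / (2 * d2) else ys[k]
      out[[length(out) + 1]] <- c(HC_NM_HARTREE / e_pk + shift, h_pk)
    }
  }
  if (length(out) == 0) {
    return(data.frame(wavelength = numeric(0), height = numeric(0)))
  }
  m <- do.call(rbind, out)
  res <- data.frame(wavelength = m[, 1], height = m[, 2])
  res[order(res$wavelength), , drop = FALSE]
}

#' Calibrate the constant wavelength shift against experiment
#'
#' Finds the constant shift (1-nm grid) minimizing the mean absolute
#' difference between shifted theoretical peak positions and experimental
#' ones; peaks are paired in wavelength order.
#'
#' @param theory_peaks numeric vector of theoretical peak wavelengths (nm),
#'   or a [find_peaks()] data frame.
#' @param experiment_peaks numeric vector of experimental peak wavelengths
#'   (nm); paired with `theory_peaks` in sorted order (extra peaks on either
#'   side are dropped).
#' @param search two-element search range for the shift in nm.
#' @return optimal shift in nm (positive = theory moves to longer
#'   wavelengths).
#' @export
calibrate_shift <- function(theory_peaks, experiment_peaks,
                            search = c(-300, 300)) {
  th <- if (is.data.frame(theory_peaks)) theory_peaks$wavelength else
    theory_peaks
  ex <- experiment_peaks
  if (length(th) == 0 || length(ex) == 0) stop("no peak pairs to calibrate on")
  th <- sort(th); ex <- sort(ex)
  k <- min(length(th), length(ex))
  th <- th[seq_len(k)]; ex <- ex[seq_len(k)]
  grid <- seq(search[1], search[2], by = 1)
  err <- vapply(grid, function(s) mean(abs(th + s - ex)), numeric(1))
  best <- which(err == min(err))
  grid[best[which.min(abs(grid[best]))]]
}

#' Apply a constant wavelength shift to a spectrum
#'
#' @param spectrum an [absorption()] result.
#' @param shift shift in nm (recorded in `shift_applied`).
#' @return shifted spectrum.
#' @export
apply_shift <- function(spectrum, shift) {
  spectrum$wavelength <- spectrum$wavelength + shift
  spectrum$shift_applied <- spectrum$shift_applied + shift
  spectrum
}

#' Per-atom absorption map at a wavelength
#'
#' Sums the per-basis-function dipole contributions to per-atom series,
#' applies the same baseline correction and damping as the total-dipole
#' transform, and reports the magnitude of the complex atomic transform
#' (Euclidean norm over the three Cartesian components) at the requested
#' wavelength.  The complex atomic transforms sum exactly to the transform
#' of the total dipole.
#'
#' @param trace a [propagate()] trace with per-basis dipole series.
#' @param wavelength wavelength in nm at which to evaluate the map.
#' @param attenuation damping rate gamma (au).
#' @param tail_fraction baseline-correction tail fraction.
#' @param energy_range_ev admissible photon-energy range; wavelengths mapping
#'   outside it are rejected.
#' @return data frame with `serial`, `element`, `x`, `y`, `z`, `magnitude`
#'   (one row per atom).
#' @export
atom_map <- function(trace, wavelength, attenuation = 0.015,
                     tail_fraction = 0.9, energy_range_ev = c(1, 35)) {
  energy <- HC_NM_HARTREE / wavelength
  grid <- energy_range_ev / HARTREE_TO_EV
  if (energy < min(grid) || energy > max(grid)) {
    stop(sprintf("wavelength %.1f nm is outside the spectral grid", wavelength))
  }
  n_atoms <- max(trace$basis_atom)
  fa <- matrix(0i, n_atoms, 3)
  for (d in 1:3) {
    pb <- trace$per_basis[[d]]
    # per-atom time series: sum of the atom's basis-function contributions
    per_atom <- t(rowsum(t(pb), group = trace$basis_atom))
    per_atom <- baseline_correct(per_atom, tail_fraction)
    ft <- damped_ft(per_atom, trace$times, attenuation, energies = energy)
    fa[, d] <- ft$transform[1, ]
  }
  mag <- sqrt(rowSums(abs(fa)^2))
  at <- trace$atoms
  if (is.null(at)) {
    return(data.frame(serial = seq_len(n_atoms), element = NA_character_,
                      x = NA_real_, y = NA_real_, z = NA_real_,
                      magnitude = mag))
  }
  data.frame(serial = at$serial, element = at$element,
             x = at$x, y = at$y, z = at$z, magnitude = mag)
}

#' Pointwise mean of several spectra
#'
#' Spectra are resampled onto the energy grid of the first one (linear
#' interpolation) where grids differ.
#'
#' @param spectra list of [absorption()] results.
#' @param scale multiplier applied to the mean (e.g. 4 for display).
#' @return an `absorption_spectrum` holding the scaled mean.
#' @export
mean_spectrum <- function(spectra, scale = 1) {
  if (length(spectra) == 0) stop("empty spectrum list")
  ref <- spectra[[1]]
  iso <- vapply(spectra, function(sp) {
    if (identical(sp$energy, ref$energy)) sp$isotropic
    else approx(sp$energy, sp$isotropic, xout = ref$energy, rule = 2)$y
  }, numeric(length(ref$energy)))
  m <- rowMeans(as.matrix(iso)) * scale
  .new_spectrum(ref$energy, matrix(m, ncol = 1), m, ref$attenuation,
                shift = ref$shift_applied, label = "mean")
}

#' Write a spectrum as delimited text
#'
#' @param spectrum an [absorption()] result.
#' @param path output path (tab-separated: wavelength_nm, energy_Ha,
#'   strength_x/y/z, isotropic).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  df <- data.frame(wavelength_nm = spectrum$wavelength,
                   energy_Ha = spectrum$energy)
  if (ncol(spectrum$strength) == 3) {
    df$strength_x <- spectrum$strength[, 1]
    df$strength_y <- spectrum$strength[, 2]
    df$strength_z <- spectrum$strength[, 3]
  }
  df$isotropic <- spectrum$isotropic
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
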