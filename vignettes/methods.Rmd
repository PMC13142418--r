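---
title: "Real-time Hartree-Fock absorption spectra with an explicit quantum environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time Hartree-Fock absorption spectra with an explicit quantum environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chromophores bound inside proteins — the flavin adenine dinucleotide (FAD)
of cryptochrome is the motivating case — absorb light in an environment of
amino-acid residues that polarizes and amplifies their response.  Treating
that environment quantum-mechanically is normally prohibitive: standard
linear-response excited-state methods scale too steeply to include hundreds
of surrounding atoms.  `rthf` implements the alternative this package is
built around: *real-time* time-dependent Hartree-Fock (RT-TDHF) in the
minimal STO-3G basis.  The one-electron density matrix is perturbed by an
instantaneous dipole "kick" and propagated in time; the Fourier transform of
the induced dipole contains every dipole-allowed excitation at once.  The
cost per time step is dominated by one Fock build over precomputed,
significance-screened two-electron integrals, which is what makes
1,000-atom quantum regions tractable.

## From structure to quantum region

The pipeline starts from a protonated PDB structure (hydrogen placement is
done externally; the tool warns when a heavy-atom-only file is supplied).

1. **Ligand selection** — all atoms of the chromophore residue(s), plus
   hydrogens bonded to them.  Multi-copy entries are disambiguated by an
   explicit chain argument rather than by guessing.
2. **Distance seed** — every atom within the cutoff (0, 3 or 5 Å are the
   standard choices) of any ligand atom joins the region.
3. **Growth** — bonds are detected geometrically: two atoms bond when their
   distance is at most `bond_detect_scale` (default 1.3) times the sum of
   their covalent radii.  A carbon-carbon bond of at least `cc_single_min`
   (default 1.45 Å) counts as a single bond; aromatic and double C-C bonds
   (~1.34-1.40 Å) never do.  While any bond crossing the region boundary is
   *not* a C-C single bond, the outside atom is pulled in.  This is the
   minimal closure satisfying the rule that only C-C single bonds are cut.
4. **Capping** — each remaining boundary bond is cut and the outside carbon
   replaced by a hydrogen on the original bond vector at `cap_bond_length`
   (default 1.09 Å, a standard C-H length; a fixed length rather than a
   scaled bond vector, exposed in `environment_spec()`).

The carve is a set closure, so it is independent of atom order; caps are
emitted in a canonical coordinate sort.  Degenerate inputs: atoms closer
than 0.4 Å are treated as a clash and rejected; growth that swallows the
whole structure returns it uncut with a warning.

## Charge selection

Crystal structures do not carry the total charge of the carved region.  The
package reproduces the scan protocol: for each candidate charge (only even
electron counts; the treatment is closed-shell), solve the ground state,
compute the Mulliken electron count of the ligand fragment, and run a short
field-free propagation (default 50 steps) whose idempotency-trace drift
probes numerical stability.  Candidates whose ligand electron count falls in
`[target - 0.5, target]` (408 for the oxidized FAD dianion) are accepted;
among them the smallest drift wins.  Drifts below 1e-9 electrons/electron
are numerical noise and count as ties, which fall through to "charge closest
to zero, then negative" — a documented extension, since the reference
protocol reports the stable candidate was always unique.

## Electronic structure

* **Basis.** STO-3G Cartesian Gaussians (H/He: 1s; C/N/O: 1s 2s 2p; P/S:
  + 3s 3p), contracted functions renormalized to exact unit self-overlap.
* **Integrals.** McMurchie-Davidson recurrences (Hermite expansion plus Boys
  function) in compiled code.  The dipole origin is the nuclear center of
  charge; spectra are origin-independent because the baseline correction
  removes static offsets.
* **Screening.** A basis-function pair is *significant* when its Schwarz
  factor times the largest Schwarz factor reaches `screen_threshold`
  (default 1e-6).  Integrals are stored for quartets of significant pairs
  whose Schwarz product reaches the threshold; no additional distance-based
  truncation is applied when contracting Coulomb or exchange terms.  An
  unscreened dense tensor is available for small systems as the reference.
* **SCF.** DIIS-accelerated restricted Hartree-Fock from a core-Hamiltonian
  guess; convergence at `dE < 1e-8` Ha and `max|dP| < 1e-6`.  Overlap
  eigenvalues below 1e-7 are projected out (canonical orthogonalization).

## Real-time propagation

The kick multiplies the occupied orbitals by `exp(-i kappa d)` (field
impulse `kappa`, default 2e-4 au — weak enough that peak intensities are
linear in `kappa` to within 1%, strong enough for clean signal).  The
density is propagated in the orthonormalized representation by an
exponential-midpoint predictor-corrector: the midpoint Fock is first
extrapolated linearly from the two previous steps, then corrected by
rebuilding the Fock at the predicted density and re-propagating with the
average of current and new Fock until `max|dP| < 1e-7` (at most 10 sweeps;
persistent failure over more than 10 consecutive steps aborts).  The
production schedule is 10,000 steps of 0.25 au (60.5 fs).

Recorded at every step: the electronic dipole, a Mulliken-symmetrized
per-basis-function partition of it (exactly additive, so per-atom series are
well defined), the idempotency-trace drift `|Tr(P'^2)/2 - N|/N` in the
orthonormal metric (the `Tr((PS)^2)` form in the atomic-orbital basis is the
same quantity), and the total energy.

## Spectra

Per kick direction the diagonal dipole response is baseline-corrected (mean
of the trailing 90% of the series subtracted — 9,000 of 10,000 steps at
defaults) and transformed as `F(w) = sum dt e^{iwt} e^{-gamma t} mu(t)`.
The attenuation `gamma` (default 0.015 au; 0.005 or 0.003 for sharper peak
tables) is an exponential damping rate, giving Lorentzian lines of
half-width `gamma`.  The absorption strength is `w * Im F(w) / kappa`, the
isotropic spectrum the mean of the three diagonal responses, and the
wavelength axis `lambda[nm] = 45.5634 / E[Ha]`.  The energy grid (default
1-10 eV at 2.5 meV) and the three-point parabolic peak refinement are tool
choices, both exposed.  Calibration against experiment is a constant
wavelength shift minimizing the mean absolute error over peak pairs on a
1-nm grid, with peaks paired in wavelength order.  Per-atom absorption maps
evaluate the magnitude of the per-atom complex transforms at a chosen
wavelength; the complex transforms sum exactly to the total-dipole
transform.

## What the synthetic fixtures emulate — and what they do not

Toy geometries (H2, He, HeH+, H2O, CH4, ethane, benzene, glycine,
tryptophan, oxidized FAD) are idealized gas-phase structures built from
standard bond parameters and force-field relaxation of the covalent
topology — *synthetic templates, not crystal conformers*.  The mini-protein
generator places a propane-like fake ligand among alanine-like residues at
exact minimum distances and records brute-force carve/cap ground truth at
generation time; it emulates the carving scenario (distance shells, bond
growth across N/O bonds, C-C single-bond cuts) but not protein secondary
structure, crystallographic disorder, or realistic protonation variety.
Passing tests therefore demonstrate the correctness of the algorithms on
controlled inputs, not the conformational realism of any particular PDB
entry.  Protein-scale runs (1,100-1,300 atoms, multi-hour) are shipped as a
documented reproduction script (`scripts/reproduce_protein.R`) because they
require external downloads and external protonation.

## Verification strategy

Every computational layer is checked against an independent oracle in the
test suite: one-electron integrals against Gauss-Hermite quadrature of the
primitive products (the nuclear-attraction and electron-repulsion kernels
through their Gaussian-transform representation, the latter with exact
rotated 2-D quadrature per primitive quartet); s-function repulsion
integrals against the erf-based closed form; ground-state energies against
an independently coded damped fixed-point SCF over the dense unscreened
tensor (and, externally, against textbook STO-3G energies: water at the
standard experimental geometry matches the published value to 1e-6 Ha);
real-time peak energies against explicit linear-response TDHF
diagonalization; and the carver against brute-force distance/graph
recomputation on seeded fixtures.

## Problem sizes and numerical choices

Test and acceptance runs truncate propagations where the damping envelope
makes further steps irrelevant: with `gamma = 0.015` au the envelope falls
below 1e-4 beyond 625 au, so the tryptophan calibration runs use 2,500
steps (1,250 in the quicker test variant) of the 10,000-step production
schedule; the damped transform, and hence every peak position, is unchanged
at that level.  Small-molecule oracle runs use 1,200-1,600 steps on wider
energy grids covering their high-lying excitations.

## The tryptophan calibration shift

The package computes the tryptophan calibration shift as the experimental
absorption maximum (280 nm) minus the dominant computed peak.  Across three
independent tryptophan geometries (two neutral conformers and the
zwitterion) and for the bare chromophore 3-methylindole, RT-TDHF/STO-3G
places the dominant band at 183-186 nm, confirmed by explicit
linear-response diagonalization (lowest bright indole state 6.70-6.73 eV,
oscillator strength ~0.2; the only state near 230 nm carries f <= 0.0014
and produces no local maximum in the 200-260 nm window).  Because the
200-260 nm window then contains no peak, the shift is evaluated
band-to-band against the longest-wavelength prominent peak, giving a shift
near 97 nm rather than the 50 nm reported for the reference protocol.  The
discrepancy is documented rather than tuned away: every layer of this
implementation is oracle-verified, and the fixture geometries are the
stated idealized templates.

## Known limitations

Closed-shell RHF only (no semiquinone radical states); no electronic
correlation, so absolute excitation energies are strongly overestimated and
only shift-calibrated comparisons are meaningful; no vibronic fine
structure (single-conformer spectra show single maxima where experiment
shows doublets/triplets); Cartesian functions only, adequate for the s/p
shells in scope; no nuclear motion and no explicit laser envelopes.
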