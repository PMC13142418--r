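#!/usr/bin/env Rscript

# Protein-scale reproduction protocol (NOT desk-scale; several hours per
# system on one node and tens of GB of memory for the integral store).
#
# Inputs you must prepare yourself (they require network access and external
# tools, and are therefore not shipped):
#   1. Download a cryptochrome structure with bound FAD from the PDB
#      (e.g. 9LPG, 6K8I, 6K8K, 6X24, 6PU0, 6WTB, 8P4X; 4GU5/6PU0 for the
#      tryptophan-tetrad systems, 2J4D for FAD+MTHF).
#   2. Add hydrogens with an external protonation tool (the reference
#      protocol used ChimeraX).  For the oxidized flavin, delete the one
#      flavin hydrogen the generic protonation adds: the oxidized state
#      carries none there.
#
# With a protonated PDB in hand, the pipeline below carves the 5-Angstrom
# environment (1,100-1,300 atoms for the tetrad/MTHF systems), scans the
# total charge against the FAD Mulliken window [407.5, 408], runs the three
# kick propagations (10,000 x 0.25 au) and writes spectrum, peak table and
# per-atom absorption maps.  Calibrating the 5-Angstrom peak positions of
# the seven cryptochrome samples against their experimental spectra yields
# the constant shift (reported as 140 nm); Table-1-style peak tables come
# from find_peaks() on the shifted spectra with attenuation 0.005.

suppressPackageStartupMessages({
  library(optparse)
  library(rthf)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--pdb", type = "character",
              help = "protonated PDB file (see header)"),
  make_option("--ligand", type = "character", default = "FAD"),
  make_option("--chain", type = "character", default = NULL),
  make_option("--cutoff", type = "double", default = 5),
  make_option("--candidates", type = "character", default = "-6:1"),
  make_option("--target", type = "double", default = 408,
              help = "ligand Mulliken electron target [default %default]"),
  make_option("--memory-gb", type = "double", default = 64),
  make_option("--out-dir", type = "character", default = "protein_run")
)))

cfg <- run_config(
  pdb = opts$pdb, ligand = opts$ligand, chain = opts$chain,
  cutoff = opts$cutoff, charge = NA_integer_,
  charge_candidates = eval(parse(text = opts$candidates)),
  target_electrons = opts$target,
  dt = 0.25, n_steps = 10000, kick_strength = 2e-4, attenuation = 0.015,
  peak_window = c(250, 650), map_wavelengths = c(368, 372),
  out_dir = opts$`out-dir`)
res <- run_pipeline(cfg)

cat(sprintf("system size: %d atoms; chosen charge %+d\n",
            nrow(res$system$atoms), res$charge))
cat("unshifted peaks (nm):\n")
print(res$peaks)
cat("\nApply the cross-sample calibration shift with apply_shift();\n")
cat("re-run find_peaks() with attenuation 0.005 for sharp peak tables.\n")
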