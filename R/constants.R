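# Physical constants (CODATA-level precision is irrelevant at STO-3G accuracy,
# but conversions must be self-consistent throughout the package).
ANGSTROM_TO_BOHR <- 1.8897259886
FS_PER_AU <- 0.02418884254      # atomic unit of time in femtoseconds
HARTREE_TO_EV <- 27.211386245
HC_NM_HARTREE <- 45.56335253    # lambda[nm] = HC_NM_HARTREE / E[Hartree]
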