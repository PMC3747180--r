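# Shared fixtures: two synthetic proteins large enough to band inside the
# default gel model (~18 and ~16 kDa), with tryptic peptides spanning the
# MALDI-observable length range.

toy_proteins <- function() {
  tibble::tibble(
    accession = c("P1", "P2"),
    sequence = c(
      paste0("MSGKEEDVRLGANKFAEQRYWDAGISGAHLTGITKAANFDQAGLVMLAR",
             "QPIGTSAQTDKDYKEPPAPLFEPGELKSWSFYRAEFIATFLFLYITVLTVMGVKR",
             "SDVETGINSLAHGYSKGTGLLIEIILTFGLVYTVYATAIDPKK"),
      paste0("MTEYKLVVVGAGGVGKSALTIQLIQNHFVDEYDPTIEDSYRKQVVIDGETCLLDILDTAGQEEYSAMR",
             "DQYMRTGEGFLCVFAINNTKSFEDIHQYREQIKRVKDSDDVPMVLVGNKCDLAAR",
             "TVESRQAQDLARSYGIPYIETSAKTR")),
    annotation = c("synthetic membrane-like protein",
                   "synthetic GTPase-like protein"))
}

# Small noiseless experiment for exact-recovery tests.
noiseless_config <- function(seed = 1, heavy_fraction = 0.5, ...) {
  simulation_config(seed = seed, proteins = toy_proteins(),
                    heavy_fraction = heavy_fraction,
                    n_spectra_per_peptide = 1,
                    intensity_cv = 0, dropout = 0, mz_jitter_ppm = 0,
                    ...)
}

# Study-condition noise at reduced replication, for stochastic tests.
noisy_config <- function(seed = 1, heavy_fraction = 0.5,
                         n_spectra_per_peptide = 3, ...) {
  simulation_config(seed = seed, proteins = toy_proteins(),
                    heavy_fraction = heavy_fraction,
                    n_spectra_per_peptide = n_spectra_per_peptide, ...)
}
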