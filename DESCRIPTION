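Package: n15quant
Title: Relative Quantification of 14N/15N Metabolically Labeled Proteins
    from MALDI Peak Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies relative protein abundance between two samples that
    were metabolically labeled with 14N and 15N, mixed, and analyzed by
    LC-MALDI-TOF mass spectrometry. Computes theoretical isotope envelopes
    for tryptic peptides at arbitrary 15N enrichment by elemental
    convolution, matches light/heavy envelope pairs in centroided peak
    lists, applies envelope-shape and positional (gel segment, LC elution)
    consistency filters, summarises heavy-fraction q-values per peptide and
    per protein, estimates 15N labeling efficiency by grid search, and
    infers isoform abundance ratios from peptides shared between family
    members. Includes a ground-truth simulator of labeled LC-MALDI
    experiments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
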