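test_that("the default proteome is a deterministic isoform family", {
  p1 <- default_proteome()
  p2 <- default_proteome()
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 16)
  fam <- p1$sequence[startsWith(p1$accession, "FAM")]
  expect_equal(length(fam), 13)
  # >= 90% identity to the base isoform, same length
  base <- strsplit(fam[1], "")[[1]]
  for (s in fam[-1]) {
    res <- strsplit(s, "")[[1]]
    expect_equal(length(res), length(base))
    expect_gte(mean(res == base), 0.90)
  }
  # the family yields both unique and shared peptides
  cls <- classify_uniqueness(build_peptide_map(p1),
                             family = p1$accession[startsWith(p1$accession,
                                                              "FAM")])
  expect_gt(sum(cls$unique), 0)
  expect_gt(sum(!cls$unique), 0)
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(default_proteome())
  invisible(simulate_experiment(noiseless_config(seed = 5)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("a fixed seed reproduces the experiment byte for byte", {
  ex1 <- simulate_experiment(noisy_config(seed = 3))
  ex2 <- simulate_experiment(noisy_config(seed = 3))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_experiment(ex1, d1)
  write_experiment(ex2, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # a different seed changes the noise
  ex3 <- simulate_experiment(noisy_config(seed = 4))
  expect_false(identical(ex1$peaklists$peaks, ex3$peaklists$peaks))
})

test_that("noiseless simulation recovers every true q exactly", {
  ex <- simulate_experiment(noiseless_config(seed = 2, heavy_fraction = 0.5))
  meas <- quantify_pairs(ex$library, ex$peaklists, ex$proteins,
                         settings = ex$config$settings,
                         gel_model = ex$config$gel_model)
  acc <- meas[meas$accepted, ]
  expect_gt(nrow(acc), 10)
  expect_equal(acc$q, rep(0.5, nrow(acc)), tolerance = 1e-12)
})

test_that("the truth table traces every emitted envelope pair", {
  ex <- simulate_experiment(noiseless_config(seed = 6, heavy_fraction = 0.3))
  expect_setequal(unique(ex$truth$spectrum), ex$peaklists$spectrum)
  expect_true(all(ex$truth$peptide %in% ex$library$peptide))
  expect_true(all(ex$truth$true_q == 0.3))
  expect_true(all(ex$truth$decoy == "none"))
})

test_that("per-protein heavy fractions mix into shared-peptide truth", {
  prots <- default_proteome(n_family = 2, n_unrelated = 0)
  f <- c(FAM01 = 0.2, FAM02 = 0.6)
  cfg <- simulation_config(seed = 9, proteins = prots, heavy_fraction = f,
                           n_spectra_per_peptide = 1, intensity_cv = 0,
                           dropout = 0, mz_jitter_ppm = 0)
  ex <- simulate_experiment(cfg)
  shared <- ex$truth[grepl(";", ex$truth$accessions), ]
  expect_gt(nrow(shared), 0)
  expect_true(all(shared$true_q == 0.4))
  uniq1 <- ex$truth$true_q[ex$truth$accessions == "FAM01"]
  expect_true(all(uniq1 == 0.2))
})

test_that("zero-confounder injection leaves the experiment unchanged", {
  ex <- simulate_experiment(noiseless_config(seed = 8))
  expect_identical(inject_confounders(ex, 0, 0), ex)
})

test_that("positional decoys are fully removed by the positional filters", {
  ex <- simulate_experiment(noiseless_config(seed = 10, heavy_fraction = 0.4))
  ex <- inject_confounders(ex, n_positional = 12, n_shape = 0)
  meas <- quantify_pairs(ex$library, ex$peaklists, ex$proteins,
                         settings = ex$config$settings,
                         gel_model = ex$config$gel_model)
  truth_decoy <- ex$truth[ex$truth$decoy == "positional",
                          c("peptide", "spectrum")]
  decoy <- dplyr::inner_join(meas, truth_decoy,
                             by = c("peptide", "spectrum"))
  expect_gt(nrow(decoy), 0)
  expect_true(all(!decoy$gel_ok | !decoy$elution_ok))
  expect_true(all(!decoy$accepted))
})

test_that("wrong-composition decoys at the right position fail the shape test", {
  ex <- simulate_experiment(noiseless_config(seed = 12, heavy_fraction = 0.4))
  ex <- inject_confounders(ex, n_positional = 0, n_shape = 12)
  meas <- quantify_pairs(ex$library, ex$peaklists, ex$proteins,
                         settings = ex$config$settings,
                         gel_model = ex$config$gel_model)
  truth_decoy <- ex$truth[ex$truth$decoy == "shape",
                          c("peptide", "spectrum")]
  decoy <- dplyr::inner_join(meas, truth_decoy,
                             by = c("peptide", "spectrum"))
  expect_gt(nrow(decoy), 0)
  expect_gte(mean(!decoy$accepted), 0.95)
  # the ratio differences themselves exceed the threshold on some side
  worst <- pmax(decoy$max_diff_light, decoy$max_diff_heavy, na.rm = TRUE)
  expect_gte(mean(worst > 0.05, na.rm = TRUE), 0.95)
})
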