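extract_self <- function(sequence, p, scale = 1) {
  comp <- composition_of(sequence)
  theo <- isotope_envelope(comp, p)
  pk <- tibble::tibble(mz = theo$mz, intensity = theo$intensity * scale)
  list(theo = theo, ext = extract_envelope(pk, theo, 30))
}

test_that("an envelope tested against itself passes at any threshold", {
  s <- extract_self("DVEGPEGFQTR", 0.982)
  v <- envelope_quality(s$ext, threshold = 1e-9)
  expect_true(v$pass)
  expect_equal(v$max_diff, 0)
})

test_that("a mis-enriched envelope fails the shape test", {
  comp <- composition_of("DVEGPEGFQTR")
  theo982 <- isotope_envelope(comp, 0.982)
  env90 <- isotope_envelope(comp, 0.90, max_peaks = 30)
  pk <- tibble::tibble(mz = env90$mz, intensity = env90$intensity)
  ext <- extract_envelope(pk, theo982, 30)
  v <- envelope_quality(ext, threshold = 0.02)
  expect_false(v$pass)
  expect_gt(v$max_diff, 0.02)
})

test_that("the shape verdict is invariant to intensity scaling", {
  a <- envelope_quality(extract_self("LGANKFAEQR", 0.5)$ext, 0.05)
  b <- envelope_quality(extract_self("LGANKFAEQR", 0.5, scale = 1e4)$ext,
                        0.05)
  expect_equal(a$differences$diff, b$differences$diff)
})

test_that("quality test rejects envelopes with fewer than two adjacent slots", {
  s <- extract_self("LGANKFAEQR", 0.982)
  ext <- s$ext
  ext$matched[] <- FALSE
  ext$matched[c(2, 4)] <- TRUE  # two slots but not adjacent
  expect_error(envelope_quality(ext), "adjacent")
})

test_that("q-value algebra matches its abundance interpretation", {
  expect_equal(q_value(100, 100), 0.5)
  expect_equal(q_value(20, 80), 0.8)
  expect_equal(q_fold(0.8), 4)
  expect_equal(q_value(37, 0), 0)
  expect_equal(q_value(0, 12), 1)
  expect_equal(q_fold(1), Inf)
  # q = 0.6 -> the heavy sample is 50% more abundant
  expect_equal(q_fold(0.6), 1.5, tolerance = 1e-12)
  expect_error(q_value(0, 0), "zero")
  expect_error(q_value(-1, 2))
})

test_that("enrichment grid search recovers the generating value", {
  s <- extract_self("DVEGPEGFQTR", 0.95)
  envs <- tibble::tibble(sequence = "DVEGPEGFQTR", envelope = list(s$ext))
  fit <- estimate_enrichment(envs, carbamidomethyl = FALSE)
  expect_equal(fit$estimate, 0.95, tolerance = 0.0011)
  expect_false(fit$boundary)
  expect_equal(nrow(fit$profile), 101)
  expect_equal(glance(fit)$n_envelopes, 1)
})

test_that("natural-abundance input pins the estimate to the grid edge", {
  comp <- composition_of("DVEGPEGFQTR")
  nat <- isotope_envelope(comp, 0.00364)
  pk <- tibble::tibble(mz = nat$mz, intensity = nat$intensity)
  ext <- extract_envelope(pk, nat, 30)
  envs <- tibble::tibble(sequence = "DVEGPEGFQTR", envelope = list(ext))
  # compare against heavy theory: the best grid fit sits at the low edge
  fit <- estimate_enrichment(envs, carbamidomethyl = FALSE)
  expect_true(fit$boundary)
  expect_equal(fit$estimate, 0.90)
  expect_error(estimate_enrichment(envs[0, ]), "No envelopes")
})

test_that("gel filter accepts monomer and dimer bands, rejects others", {
  gm <- tibble::tibble(segment = 0:2,
                       mw_lo = c(55, 25, 10), mw_hi = c(65, 35, 25))
  # 30 kDa protein in its 25-35 kDa segment: monomer fit
  f <- positional_filters(1, 10, 1, 2, protein_mass_kda = 30,
                          gel_model = gm)
  expect_true(f$gel_ok)
  # same protein in the 55-65 kDa segment: dimer fit
  f2 <- positional_filters(0, 10, 0, 2, protein_mass_kda = 30,
                           gel_model = gm)
  expect_true(f2$gel_ok)
  # a 15 kDa protein can't reach 55-65 even as a dimer
  f3 <- positional_filters(0, 10, 0, 2, protein_mass_kda = 15,
                           gel_model = gm)
  expect_false(f3$gel_ok)
  # segment neighborhood: quant two segments away fails
  f4 <- positional_filters(2, 10, 0, 2, protein_mass_kda = 15,
                           gel_model = gm)
  expect_false(f4$gel_ok)
  expect_error(positional_filters(9, 10, 0, 2, protein_mass_kda = 30,
                                  gel_model = gm), "outside")
})

test_that("elution filter compares mid-fraction times across schedules", {
  # ID fraction 17 on the 48 schedule is 40.25 min; quant fraction 82 on
  # the 192 schedule is 40.375 min: within 1.5 min
  gm <- gel_model_log()
  seg <- gel_segment_for_mass(gm, 30)
  f <- positional_filters(seg, 82, seg, 17, protein_mass_kda = 30,
                          gel_model = gm, elution_tol_min = 1.5)
  expect_true(f$elution_ok)
  # ~45 min elutes too far from a 40.25 min identification
  f2 <- positional_filters(seg, 113, seg, 17, protein_mass_kda = 30,
                           gel_model = gm, elution_tol_min = 1.5)
  expect_false(f2$elution_ok)
})

test_that("tightening thresholds never grows the accepted set", {
  ex <- simulate_experiment(noisy_config(seed = 11, heavy_fraction = 0.4))
  loose <- simulation_config(seed = 11, proteins = toy_proteins())$settings
  tight <- loose
  tight$ratio_threshold <- loose$ratio_threshold / 5
  tight$elution_tol_min <- 0.2
  m_loose <- quantify_pairs(ex$library, ex$peaklists, ex$proteins, loose)
  m_tight <- quantify_pairs(ex$library, ex$peaklists, ex$proteins, tight)
  key <- function(m) paste(m$peptide, m$spectrum)[m$accepted]
  expect_true(all(key(m_tight) %in% key(m_loose)))
  expect_lte(length(key(m_tight)), length(key(m_loose)))
})

test_that("peptide aggregation reports mean, SD and spectrum counts", {
  meas <- tibble::tibble(
    peptide = c("AAA", "AAA", "AAA", "BBB"),
    accessions = c("P1", "P1", "P1", "P1;P2"),
    unique = c(TRUE, TRUE, TRUE, FALSE),
    q = c(0.30, 0.29, 0.31, 0.5),
    accepted = TRUE)
  pep <- aggregate_peptides(meas)
  row <- pep[pep$peptide == "AAA", ]
  expect_equal(row$mean_q, 0.30)
  expect_equal(row$n_spectra, 3L)
  expect_equal(row$sd_q, sd(c(0.30, 0.29, 0.31)))
  expect_equal(pep$sd_q[pep$peptide == "BBB"], 0)  # single spectrum
})

test_that("protein aggregation uses unique peptides only", {
  pep <- tibble::tibble(
    peptide = c("AAA", "CCC", "BBB"),
    accessions = c("P1", "P1", "P1;P2"),
    unique = c(TRUE, TRUE, FALSE),
    mean_q = c(0.30, 0.29, 0.99),
    sd_q = c(0.04, 0.02, 0.01),
    n_spectra = c(104L, 47L, 3L))
  prot <- aggregate_proteins(pep)
  expect_equal(nrow(prot), 1)
  expect_equal(prot$mean_q, mean(c(0.30, 0.29)))
  expect_equal(prot$sd_q, sd(c(0.30, 0.29)))
  expect_equal(prot$n_peptides, 2L)
  expect_equal(prot$n_spectra, 151L)
  # single unique peptide: the peptide's own spectrum SD is reported
  solo <- aggregate_proteins(pep[2:3, ])
  expect_equal(solo$sd_q, 0.02)
})

test_that("settings round-trip through YAML and reject unknown keys", {
  s <- default_settings()
  s$ppm_tol <- 25
  path <- withr::local_tempfile(fileext = ".yaml")
  write_settings(s, path)
  back <- read_settings(path)
  expect_equal(back[order(names(back))], s[order(names(s))])
  writeLines("not_a_setting: 1", path)
  expect_error(read_settings(path), "Unknown settings")
})
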