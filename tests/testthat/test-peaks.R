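make_spectrum_tibble <- function(mz, intensity, spectrum = "s1",
                                 lc_fraction = 10L, gel_segment = 5L) {
  tibble::tibble(spectrum = spectrum, run = "r1",
                 lc_fraction = lc_fraction, gel_segment = gel_segment,
                 peaks = list(tibble::tibble(mz = mz,
                                             intensity = intensity)))
}

test_that("peak lists round-trip through the TSV dialect", {
  pl <- dplyr::bind_rows(
    make_spectrum_tibble(c(1000.1, 1001.1, 1002.1), c(5, 10, 2)),
    make_spectrum_tibble(numeric(0), numeric(0), spectrum = "s2"))
  dir <- withr::local_tempdir()
  write_peaklists(pl, dir)
  back <- read_peaklists(dir)
  expect_equal(as.data.frame(back), as.data.frame(pl))
})

test_that("unsorted input peaks are sorted on load", {
  dir <- withr::local_tempdir()
  writeLines(c("# spectrum: s1", "# run: r1", "# lc_fraction: 3",
               "# gel_segment: 7", "1002\t1", "1000\t2", "1001\t3"),
             file.path(dir, "s1.tsv"))
  got <- read_peaklists(dir)$peaks[[1]]
  expect_equal(got$mz, c(1000, 1001, 1002))
  expect_equal(got$intensity, c(2, 3, 1))
})

test_that("missing metadata and malformed lines are reported", {
  dir <- withr::local_tempdir()
  writeLines(c("# spectrum: s1", "# run: r1", "1000\t1"),
             file.path(dir, "bad.tsv"))
  expect_error(read_peaklists(dir), "lc_fraction")
  writeLines(c("# spectrum: s1", "# run: r1", "# lc_fraction: 1",
               "# gel_segment: 1", "1000 1"),
             file.path(dir, "bad.tsv"))
  expect_error(read_peaklists(dir), "malformed|line")
})

test_that("the MGF-like container parses with fraction/segment tags", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS",
               "TITLE=spectrum=sA run=r1 lc_fraction=4 gel_segment=9",
               "1000.5 12.5", "1001.5 6.25", "END IONS"), path)
  got <- read_peaklists(path)
  expect_equal(got$spectrum, "sA")
  expect_equal(got$lc_fraction, 4L)
  expect_equal(got$gel_segment, 9L)
  expect_equal(got$peaks[[1]]$mz, c(1000.5, 1001.5))
})

test_that("fraction schedules give mid-fraction times", {
  expect_equal(fraction_time(schedule_48(), 0), 28.35)
  expect_equal(fraction_time(schedule_192(), 0), 28.075)
  # the last 48-schedule fraction ends near the stated 61-minute window
  expect_equal(fraction_time(schedule_48(), 47), 28 + 47.5 * 0.7)
  expect_error(fraction_time(schedule_48(), 48), "outside")
  expect_error(fraction_time(schedule_48(), -1), "outside")
})

test_that("envelope extraction recovers exact synthetic peaks", {
  comp <- composition_of("LGANKFAEQR")
  theo <- isotope_envelope(comp, 0.00364)
  pk <- tibble::tibble(mz = theo$mz, intensity = theo$intensity * 500)
  ext <- extract_envelope(pk, theo, ppm_tol = 30)
  expect_true(all(ext$matched))
  expect_equal(ext$intensity_obs, theo$intensity * 500)
  expect_equal(ext$nominal, theo$nominal)
})

test_that("a spectrum shifted beyond tolerance yields no envelope", {
  comp <- composition_of("LGANKFAEQR")
  theo <- isotope_envelope(comp, 0.00364)
  shifted <- tibble::tibble(mz = theo$mz * (1 + 60e-6),
                            intensity = theo$intensity)
  expect_null(extract_envelope(shifted, theo, ppm_tol = 30))
})

test_that("equidistant candidate peaks resolve to the more intense one", {
  theo <- isotope_envelope(composition_of("LGANKFAEQR"), 0.00364)
  d <- theo$mz[1] * 10e-6
  pk <- tibble::tibble(
    mz = c(theo$mz[1] - d, theo$mz[1] + d, theo$mz[-1]),
    intensity = c(1, 9, theo$intensity[-1]))
  ext <- extract_envelope(pk, theo, ppm_tol = 30)
  expect_equal(ext$intensity_obs[1], 9)
})

test_that("extraction ignores peaks far from the window and scales linearly", {
  comp <- composition_of("YWDAGISGAHLTGITK")
  theo <- isotope_envelope(comp, 0.982)
  pk <- tibble::tibble(mz = theo$mz, intensity = theo$intensity)
  with_far <- dplyr::arrange(
    dplyr::bind_rows(pk, tibble::tibble(mz = theo$mz + 25,
                                        intensity = rep(99, nrow(theo)))),
    mz)
  a <- extract_envelope(pk, theo, 30)
  b <- extract_envelope(with_far, theo, 30)
  expect_equal(a$intensity_obs, b$intensity_obs)
  scaled <- extract_envelope(
    dplyr::mutate(pk, intensity = intensity * 7.5), theo, 30)
  expect_equal(scaled$intensity_obs, a$intensity_obs * 7.5)
})

test_that("the min_matched rule requires a run through the apex slot", {
  theo <- isotope_envelope(composition_of("YWDAGISGAHLTGITK"), 0.982)
  apex <- which.max(theo$intensity)
  # remove the apex peak: no extraction even though 7 slots remain
  pk <- tibble::tibble(mz = theo$mz[-apex], intensity = theo$intensity[-apex])
  expect_null(extract_envelope(pk, theo, 30, min_matched = 3))
  # apex plus one neighbor only: below min_matched = 3
  keep <- c(apex, apex + 1)
  pk2 <- tibble::tibble(mz = theo$mz[keep], intensity = theo$intensity[keep])
  expect_null(extract_envelope(pk2, theo, 30, min_matched = 3))
  expect_false(is.null(extract_envelope(pk2, theo, 30, min_matched = 2)))
})
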