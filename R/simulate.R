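# Ground-truth simulator: a synthetic labeled proteome and the LC-MALDI
# peak lists an identification + quantification experiment would produce
# from it, with every generated q-value recorded in a truth table. All
# sequences are synthetic; the default proteome imitates a 13-member
# aquaporin-like isoform family at >= 90% identity to exercise unique/shared
# peptide classification.

# Kyte-Doolittle hydropathy index; the elution-order proxy.
KD_INDEX <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

# Run code under a given RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic synthetic protein: residues drawn at typical frequencies
# with cleavage sites (K/R, never followed by P) spaced to give tryptic
# peptides mostly 6-18 residues long.
random_protein <- function(length_target) {
  alphabet <- names(KD_INDEX)
  freq <- c(A = 8, R = 0, N = 4, D = 5, C = 1, Q = 4, E = 6, G = 7, H = 2,
            I = 5, L = 9, K = 0, M = 2, F = 4, P = 4, S = 7, T = 6, W = 1,
            Y = 3, V = 7)  # K/R placed explicitly at spacings below
  res <- character(0)
  while (length(res) < length_target) {
    span <- sample(6:18, 1)
    body <- sample(alphabet, span, replace = TRUE, prob = freq[alphabet])
    body[1] <- sample(setdiff(alphabet, "P"), 1)  # keep the K/R site cleavable
    res <- c(res, body, sample(c("K", "R"), 1))
  }
  paste(res[seq_len(length_target)], collapse = "")
}

#' Default synthetic proteome
#'
#' A 13-member isoform family derived from one ~280-residue base protein by
#' point mutations at non-site positions (identity >= 90%, cleavage pattern
#' preserved so peptides align across isoforms), plus a few unrelated
#' proteins of different molecular weight. Fully deterministic; does not
#' disturb the caller's RNG state.
#'
#' @param n_family Number of family isoforms (default 13).
#' @param n_unrelated Number of unrelated background proteins.
#' @param base_length Base protein length in residues.
#' @return A protein tibble (`accession`, `sequence`, `annotation`).
#' @export
default_proteome <- function(n_family = 13, n_unrelated = 3,
                             base_length = 280) {
  with_seed(20130712, {
    base <- random_protein(base_length)
    res0 <- strsplit(base, "")[[1]]
    mutable <- which(!res0 %in% c("K", "R", "P"))
    fam <- lapply(seq_len(n_family), function(i) {
      res <- res0
      if (i > 1) {
        pos <- sample(mutable, 8)
        for (p in pos) {
          res[p] <- sample(setdiff(names(KD_INDEX),
                                   c("K", "R", "P", res[p])), 1)
        }
      }
      paste(res, collapse = "")
    })
    unrel <- lapply(seq_len(n_unrelated), function(i) {
      random_protein(150 + 130 * i)
    })
    tibble(
      accession = c(sprintf("FAM%02d", seq_len(n_family)),
                    sprintf("BKG%02d", seq_len(n_unrelated))),
      sequence = unlist(c(fam, unrel)),
      annotation = c(rep("synthetic aquaporin-like isoform", n_family),
                     rep("synthetic background protein", n_unrelated)))
  })
}

# Mid-gradient elution time (minutes) from mean hydropathy; any monotone
# proxy works since only ID/quant consistency matters.
elution_time <- function(peptide) {
  res <- strsplit(peptide, "")[[1]]
  28 + 28.4 * stats::plogis(mean(KD_INDEX[res]))
}

#' Simulation configuration
#'
#' Bundles every knob of the simulator. Defaults reproduce the study
#' conditions of a 14N/15N plant labeling experiment: 98.2% enrichment,
#' a 48-fraction identification schedule and a 192-fraction quantification
#' schedule, 2% multiplicative intensity noise (log-normal), 5 ppm m/z
#' jitter, 1% peak dropout, and a 36-segment gel model.
#'
#' @param seed Integer seed; a fixed seed makes the whole experiment
#'   byte-identical.
#' @param proteins Protein tibble; default [default_proteome()].
#' @param enrichment 15N fraction of the labeled sample.
#' @param heavy_fraction True heavy fraction f (the true q): scalar or a
#'   named vector by accession.
#' @param n_spectra_per_peptide Replicate quantification spectra per
#'   (segment, fraction) group.
#' @param base_intensity Mean total pair intensity (arbitrary units).
#' @param intensity_cv Multiplicative intensity coefficient of variation.
#' @param dropout Per-peak dropout probability.
#' @param mz_jitter_ppm Uniform m/z jitter half-width (ppm).
#' @param additive_floor Upper bound of uniform additive intensity noise.
#' @param decoy_density Random background peaks added per spectrum.
#' @param id_schedule,quant_schedule Fraction schedules of the two runs.
#' @param gel_model Segment-to-MW map.
#' @param settings Analysis settings (used for digestion parameters).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              proteins = default_proteome(),
                              enrichment = 0.982,
                              heavy_fraction = 0.5,
                              n_spectra_per_peptide = 3,
                              base_intensity = 1000,
                              intensity_cv = 0.02,
                              dropout = 0.01,
                              mz_jitter_ppm = 5,
                              additive_floor = 0,
                              decoy_density = 0,
                              id_schedule = schedule_48(),
                              quant_schedule = schedule_192(),
                              gel_model = gel_model_log(),
                              settings = default_settings()) {
  stopifnot(all(heavy_fraction >= 0), all(heavy_fraction <= 1),
            intensity_cv >= 0, dropout >= 0, dropout <= 1,
            mz_jitter_ppm >= 0, enrichment >= 0, enrichment <= 1,
            n_spectra_per_peptide >= 1)
  structure(list(seed = as.integer(seed), proteins = proteins,
                 enrichment = enrichment, heavy_fraction = heavy_fraction,
                 n_spectra_per_peptide = n_spectra_per_peptide,
                 base_intensity = base_intensity,
                 intensity_cv = intensity_cv, dropout = dropout,
                 mz_jitter_ppm = mz_jitter_ppm,
                 additive_floor = additive_floor,
                 decoy_density = decoy_density,
                 id_schedule = id_schedule, quant_schedule = quant_schedule,
                 gel_model = gel_model, settings = settings),
            class = "simulation_config")
}

#' Simulate a full labeling experiment
#'
#' Digests the configured proteome, builds the identification library
#' (gel segment from protein molecular weight, LC fraction from a
#' hydropathy elution proxy on the identification schedule), and writes
#' quantification-run spectra on the finer schedule, each containing the
#' light envelope scaled to `(1 - f)` and the heavy envelope scaled to `f`
#' of the peptide's total intensity, with the configured noise. A truth
#' table records every generated envelope pair.
#'
#' @param config A [simulation_config()].
#' @return A list of class `n15_experiment`: `proteins`, `library`,
#'   `peaklists`, `truth`, `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  s <- config$settings
  pmap <- build_peptide_map(config$proteins, max_missed = s$max_missed,
                            min_length = s$min_length,
                            max_length = s$max_length,
                            carbamidomethyl = s$carbamidomethyl)
  # drop missed-cleavage duplicates that fully contain another peptide's
  # envelope target? No: keep all, as the real library would.
  prot_mass <- setNames(
    vapply(config$proteins$sequence,
           function(x) monoisotopic_mass(composition_of(x)) / 1000,
           numeric(1)),
    config$proteins$accession)
  f_of <- function(accessions) {
    acc <- strsplit(accessions, ";")[[1]]
    f <- config$heavy_fraction
    if (!is.null(names(f))) {
      f <- f[acc]
      if (anyNA(f)) abort("heavy_fraction missing for some accessions")
    }
    mean(rep_len(f, length(acc)))
  }
  lib <- pmap |>
    dplyr::mutate(
      first_parent = vapply(strsplit(.data$accessions, ";"), `[`, "", 1),
      protein_mw = prot_mass[.data$first_parent],
      id_segment = gel_segment_for_mass(config$gel_model, .data$protein_mw),
      rt = vapply(.data$peptide, elution_time, numeric(1)),
      id_fraction = pmin(config$id_schedule$n_fractions - 1L,
                         as.integer(floor((.data$rt - config$id_schedule$start) /
                                            config$id_schedule$interval))),
      quant_fraction = pmin(config$quant_schedule$n_fractions - 1L,
                            as.integer(floor((.data$rt - config$quant_schedule$start) /
                                               config$quant_schedule$interval))),
      true_q = vapply(.data$accessions, f_of, numeric(1)))

  with_seed(config$seed, {
    groups <- dplyr::group_split(lib,
                                 .data$id_segment, .data$quant_fraction)
    speclist <- list()
    truthlist <- list()
    for (g in groups) {
      for (rep_i in seq_len(config$n_spectra_per_peptide)) {
        sid <- sprintf("s_g%02d_f%03d_r%d",
                       g$id_segment[1], g$quant_fraction[1], rep_i)
        mz <- numeric(0); int <- numeric(0)
        for (j in seq_len(nrow(g))) {
          comp <- composition_of(g$peptide[j],
                                 carbamidomethyl = s$carbamidomethyl)
          amp <- config$base_intensity *
            exp(rnorm(1, 0, 0.25 * (config$intensity_cv > 0)))
          f <- g$true_q[j]
          for (side in c("light", "heavy")) {
            env <- isotope_envelope(
              comp,
              if (side == "light") s$natural_n15 else config$enrichment,
              s$max_peaks)
            scale <- amp * if (side == "light") (1 - f) else f
            if (scale <= 0) next
            keep <- runif(nrow(env)) >= config$dropout
            noise <- if (config$intensity_cv > 0) {
              exp(rnorm(nrow(env), 0,
                        sqrt(log(1 + config$intensity_cv^2))))
            } else rep(1, nrow(env))
            add <- if (config$additive_floor > 0) {
              runif(nrow(env), 0, config$additive_floor)
            } else 0
            jit <- if (config$mz_jitter_ppm > 0) {
              1 + runif(nrow(env), -config$mz_jitter_ppm,
                        config$mz_jitter_ppm) * 1e-6
            } else 1
            mz <- c(mz, (env$mz * jit)[keep])
            int <- c(int, (env$intensity * scale * noise + add)[keep])
          }
          truthlist[[length(truthlist) + 1]] <- tibble(
            peptide = g$peptide[j], accessions = g$accessions[j],
            spectrum = sid, true_q = f,
            enrichment = config$enrichment,
            gel_segment = g$id_segment[j],
            lc_fraction = g$quant_fraction[j],
            decoy = "none")
        }
        if (config$decoy_density > 0) {
          n_bg <- rbinom(1, 10 * config$decoy_density, 0.1)
          mz <- c(mz, runif(n_bg, 800, 3500))
          int <- c(int, runif(n_bg, 0, config$base_intensity / 10))
        }
        ord <- order(mz)
        speclist[[length(speclist) + 1]] <- tibble(
          spectrum = sid, run = "quant1",
          lc_fraction = g$quant_fraction[1],
          gel_segment = g$id_segment[1],
          peaks = list(tibble(mz = mz[ord], intensity = int[ord])))
      }
    }
    structure(list(
      proteins = config$proteins,
      library = dplyr::select(lib, "peptide", "accessions", "unique",
                              "missed", "id_segment", "id_fraction"),
      peaklists = dplyr::bind_rows(speclist),
      truth = dplyr::bind_rows(truthlist),
      config = config),
      class = "n15_experiment")
  })
}

#' Inject known false-positive confounders into an experiment
#'
#' Adds decoy spectra that exercise the two filter stages: "positional"
#' decoys carry a correct envelope pair but sit in the wrong gel segment or
#' elute at the wrong LC position (they must be removed by the positional
#' filters); "shape" decoys sit at the correct position and the correct
#' masses but carry the envelope of a different (here: atom-doubled)
#' composition (they must be removed by the envelope-shape test). Decoy
#' provenance is recorded in the truth table.
#'
#' @param experiment An `n15_experiment` from [simulate_experiment()].
#' @param n_positional,n_shape Number of decoy spectra of each kind.
#' @return The experiment with decoy spectra and truth rows appended.
#' @export
inject_confounders <- function(experiment, n_positional = 20, n_shape = 20) {
  stopifnot(inherits(experiment, "n15_experiment"))
  if (n_positional == 0 && n_shape == 0) return(experiment)
  config <- experiment$config
  s <- config$settings
  lib <- experiment$library
  n_seg <- nrow(config$gel_model)
  # LC-fraction shift guaranteed to violate the elution tolerance
  frac_shift <- ceiling((2 * s$elution_tol_min) /
                          config$quant_schedule$interval) + 5L
  make_spectrum <- function(peptide, sid, segment, fraction, shape_decoy) {
    comp <- composition_of(peptide, carbamidomethyl = s$carbamidomethyl)
    light <- isotope_envelope(comp, s$natural_n15, s$max_peaks)
    heavy <- isotope_envelope(comp, config$enrichment, s$max_peaks)
    if (shape_decoy) {
      wrong <- comp * 2L  # atom-doubled composition: same masses, wrong shape
      wl <- isotope_envelope(wrong, s$natural_n15, s$max_peaks + 8)
      wh <- isotope_envelope(wrong, config$enrichment, s$max_peaks + 8)
      light$intensity <- wl$intensity[seq_len(nrow(light))] /
        sum(wl$intensity[seq_len(nrow(light))])
      heavy$intensity <- wh$intensity[seq_len(nrow(heavy))] /
        sum(wh$intensity[seq_len(nrow(heavy))])
    }
    amp <- config$base_intensity
    pk <- tibble(
      mz = c(light$mz, heavy$mz),
      intensity = c(light$intensity, heavy$intensity) * amp * 0.5)
    pk <- pk[order(pk$mz), ]
    tibble(spectrum = sid, run = "quant1",
           lc_fraction = as.integer(fraction),
           gel_segment = as.integer(segment), peaks = list(pk))
  }
  new_specs <- list()
  new_truth <- list()
  add <- function(spec, peptide, accessions, kind) {
    new_specs[[length(new_specs) + 1]] <<- spec
    new_truth[[length(new_truth) + 1]] <<- tibble(
      peptide = peptide, accessions = accessions,
      spectrum = spec$spectrum, true_q = NA_real_,
      enrichment = config$enrichment,
      gel_segment = spec$gel_segment, lc_fraction = spec$lc_fraction,
      decoy = kind)
  }
  for (i in seq_len(n_positional)) {
    entry <- lib[1 + (i - 1) %% nrow(lib), ]
    rt <- elution_time(entry$peptide)
    qf <- min(config$quant_schedule$n_fractions - 1,
              floor((rt - config$quant_schedule$start) /
                      config$quant_schedule$interval))
    if (i %% 2 == 1) {  # wrong gel segment (beyond the +-1 neighborhood)
      seg <- (entry$id_segment + 5) %% n_seg
      add(make_spectrum(entry$peptide, sprintf("decoy_pos_%03d", i),
                        seg, qf, FALSE),
          entry$peptide, entry$accessions, "positional")
    } else {            # wrong LC fraction
      frac <- (qf + frac_shift) %% config$quant_schedule$n_fractions
      add(make_spectrum(entry$peptide, sprintf("decoy_pos_%03d", i),
                        entry$id_segment, frac, FALSE),
          entry$peptide, entry$accessions, "positional")
    }
  }
  for (i in seq_len(n_shape)) {
    entry <- lib[1 + (i - 1) %% nrow(lib), ]
    rt <- elution_time(entry$peptide)
    qf <- min(config$quant_schedule$n_fractions - 1,
              floor((rt - config$quant_schedule$start) /
                      config$quant_schedule$interval))
    add(make_spectrum(entry$peptide, sprintf("decoy_shape_%03d", i),
                      entry$id_segment, qf, TRUE),
        entry$peptide, entry$accessions, "shape")
  }
  experiment$peaklists <- dplyr::bind_rows(experiment$peaklists,
                                           dplyr::bind_rows(new_specs))
  experiment$truth <- dplyr::bind_rows(experiment$truth,
                                       dplyr::bind_rows(new_truth))
  experiment
}

#' Write a simulated experiment to disk
#'
#' Emits the canonical artifacts: `proteins.fasta`, `library.tsv`, a
#' `peaks/` directory in the TSV peak-list dialect, `truth.tsv` and
#' `settings.yaml`.
#'
#' @param experiment An `n15_experiment`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(experiment$proteins, file.path(dir, "proteins.fasta"))
  readr::write_tsv(experiment$library, file.path(dir, "library.tsv"))
  write_peaklists(experiment$peaklists, file.path(dir, "peaks"))
  readr::write_tsv(experiment$truth, file.path(dir, "truth.tsv"))
  write_settings(experiment$config$settings, file.path(dir, "settings.yaml"))
  invisible(dir)
}
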