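# The full quantification pipeline: for every library peptide, search every
# quantification spectrum for the light/heavy envelope pair, apply shape and
# positional filters, and aggregate accepted q-values.

#' Match and quantify light/heavy peptide pairs
#'
#' For each peptide in the identification library, computes the theoretical
#' light (natural-abundance) and heavy (enriched) envelopes and searches
#' every quantification spectrum for them. Each found pair (or single side)
#' becomes one measurement row carrying the q-value, the two envelope
#' quality verdicts, the positional-filter flags, the overlap flag, and the
#' resulting acceptance decision.
#'
#' A peptide observed with only one envelope side is reported as q exactly
#' 0 (light only) or 1 (heavy only); such single-tissue calls still must
#' pass the quality verdict of the observed side and both positional
#' filters. Spectra in which one observed peak is claimed by both the light
#' and the heavy envelope (possible for low-nitrogen peptides whose windows
#' touch) are flagged as overlapping and excluded from aggregation.
#'
#' @param library Identification library: tibble with columns `peptide`,
#'   `accessions` (semicolon-joined), `unique`, `id_segment`, `id_fraction`.
#' @param peaklists Spectra tibble from [read_peaklists()] (the mixed
#'   light/heavy quantification run).
#' @param proteins Protein table (`accession`, `sequence`) used for intact
#'   masses in the gel filter.
#' @param settings Settings list, see [default_settings()].
#' @param gel_model Segment-to-MW map, see [gel_model_log()].
#' @param id_schedule,quant_schedule Fraction schedules of the
#'   identification and quantification runs.
#' @return A tibble with one row per (peptide, spectrum) measurement.
#' @export
quantify_pairs <- function(library, peaklists, proteins,
                           settings = default_settings(),
                           gel_model = gel_model_log(),
                           id_schedule = schedule_48(),
                           quant_schedule = schedule_192()) {
  validate_settings(settings)
  need <- c("peptide", "accessions", "unique", "id_segment", "id_fraction")
  if (!all(need %in% names(library))) {
    abort(paste0("Library lacks columns: ",
                 paste(setdiff(need, names(library)), collapse = ", ")))
  }
  protein_mass <- setNames(
    vapply(proteins$sequence,
           function(s) monoisotopic_mass(composition_of(s)) / 1000,
           numeric(1)),
    proteins$accession)

  # theoretical envelopes once per peptide
  targets <- lapply(seq_len(nrow(library)), function(i) {
    pep <- library$peptide[i]
    comp <- composition_of(pep, carbamidomethyl = settings$carbamidomethyl)
    light <- isotope_envelope(comp, settings$natural_n15, settings$max_peaks)
    heavy <- isotope_envelope(comp, settings$enrichment, settings$max_peaks)
    list(peptide = pep, comp = comp, light = light, heavy = heavy,
         mz_lo = min(light$mz) - 1, mz_hi = max(heavy$mz) + 1)
  })

  rows <- vector("list", 0)
  for (sp in seq_len(nrow(peaklists))) {
    spec <- peaklists[sp, ]
    pk <- spec$peaks[[1]]
    if (!nrow(pk)) next
    for (tg in targets) {
      # quick window pre-check before slot-level matching
      if (!any(pk$mz >= tg$mz_lo & pk$mz <= tg$mz_hi)) next
      le <- extract_envelope(pk, tg$light, settings$ppm_tol,
                             settings$min_matched)
      he <- extract_envelope(pk, tg$heavy, settings$ppm_tol,
                             settings$min_matched)
      if (is.null(le) && is.null(he)) next
      # A single-side (q = 0 or 1) call requires the partner side to be
      # truly absent: partial partner signal that merely failed the
      # consecutive-slot rule makes the spectrum ambiguous, not a call.
      ambiguous <- (is.null(le) &&
                      n_slots_matched(pk, tg$light, settings$ppm_tol) > 0) ||
                   (is.null(he) &&
                      n_slots_matched(pk, tg$heavy, settings$ppm_tol) > 0)
      overlap <- FALSE
      if (!is.null(le) && !is.null(he)) {
        # both envelopes live on the same unit-mass grid; a nominal slot
        # matched by both means the light tail reaches the heavy window
        shared <- intersect(le$nominal[le$matched], he$nominal[he$matched])
        if (length(shared)) {
          overlap <- TRUE
          # assign each contested slot to the nearer theoretical position
          for (b in shared) {
            li <- which(le$matched & le$nominal == b)
            hi <- which(he$matched & he$nominal == b)
            dl <- abs(le$mz_obs[li] - le$mz_theo[li])
            dh <- abs(he$mz_obs[hi] - he$mz_theo[hi])
            if (dl <= dh) {
              he$matched[hi] <- FALSE
              he$intensity_obs[hi] <- NA_real_
            } else {
              le$matched[li] <- FALSE
              le$intensity_obs[li] <- NA_real_
            }
          }
        }
      }
      verdict <- function(env) {
        if (is.null(env) || sum(env$matched) < 2) return(NULL)
        tryCatch(envelope_quality(env, settings$ratio_threshold),
                 error = function(e) NULL)
      }
      vl <- verdict(le)
      vh <- verdict(he)
      light_sum <- if (is.null(le)) 0 else sum(le$intensity_obs[le$matched])
      heavy_sum <- if (is.null(he)) 0 else sum(he$intensity_obs[he$matched])
      if (light_sum + heavy_sum <= 0) next
      q <- q_value(light_sum, heavy_sum)
      if (isTRUE(settings$label_swap)) q <- 1 - q
      entry <- library[library$peptide == tg$peptide, ][1, ]
      acc_list <- strsplit(entry$accessions, ";")[[1]]
      masses <- protein_mass[intersect(acc_list, names(protein_mass))]
      if (!length(masses)) {
        abort(paste0("No protein sequence for accessions of peptide ",
                     tg$peptide))
      }
      pos <- positional_filters(
        quant_segment = spec$gel_segment,
        quant_fraction = spec$lc_fraction,
        id_segment = entry$id_segment,
        id_fraction = entry$id_fraction,
        quant_schedule = quant_schedule,
        id_schedule = id_schedule,
        protein_mass_kda = masses,
        gel_model = gel_model,
        elution_tol_min = settings$elution_tol_min,
        multimers = settings$multimers,
        segment_neighborhood = settings$segment_neighborhood)
      pass_light <- if (is.null(le)) NA else !is.null(vl) && vl$pass
      pass_heavy <- if (is.null(he)) NA else !is.null(vh) && vh$pass
      quality_ok <- !isFALSE(pass_light) && !isFALSE(pass_heavy) &&
        !(is.na(pass_light) && is.na(pass_heavy))
      accepted <- quality_ok && pos$gel_ok && pos$elution_ok && !overlap &&
        !ambiguous
      rows[[length(rows) + 1]] <- tibble(
        peptide = tg$peptide,
        accessions = entry$accessions,
        unique = entry$unique,
        spectrum = spec$spectrum,
        run = spec$run,
        lc_fraction = spec$lc_fraction,
        gel_segment = spec$gel_segment,
        light_sum = light_sum,
        heavy_sum = heavy_sum,
        q = q,
        fold = q_fold(q),
        pass_light = pass_light,
        pass_heavy = pass_heavy,
        max_diff_light = if (is.null(vl)) NA_real_ else vl$max_diff,
        max_diff_heavy = if (is.null(vh)) NA_real_ else vh$max_diff,
        gel_ok = pos$gel_ok,
        elution_ok = pos$elution_ok,
        overlap = overlap,
        ambiguous = ambiguous,
        uncertain = q > settings$uncertain_hi | q < settings$uncertain_lo,
        accepted = accepted)
    }
  }
  if (!length(rows)) return(empty_measurements())
  dplyr::bind_rows(rows)
}

empty_measurements <- function() {
  tibble(peptide = character(), accessions = character(), unique = logical(),
         spectrum = character(), run = character(), lc_fraction = integer(),
         gel_segment = integer(), light_sum = numeric(),
         heavy_sum = numeric(), q = numeric(), fold = numeric(),
         pass_light = logical(), pass_heavy = logical(),
         max_diff_light = numeric(), max_diff_heavy = numeric(),
         gel_ok = logical(), elution_ok = logical(), overlap = logical(),
         ambiguous = logical(), uncertain = logical(), accepted = logical())
}

#' Collect experimental heavy envelopes for enrichment estimation
#'
#' Extracts the heavy-side envelope of every library peptide from every
#' spectrum (using the settings' nominal enrichment to position the search
#' window) and returns the matches in the form [estimate_enrichment()]
#' consumes.
#'
#' @inheritParams quantify_pairs
#' @return A tibble with columns `sequence`, `spectrum` and list-column
#'   `envelope`.
#' @export
collect_heavy_envelopes <- function(library, peaklists,
                                    settings = default_settings()) {
  rows <- list()
  for (i in seq_len(nrow(library))) {
    pep <- library$peptide[i]
    comp <- composition_of(pep, carbamidomethyl = settings$carbamidomethyl)
    heavy <- isotope_envelope(comp, settings$enrichment, settings$max_peaks)
    for (sp in seq_len(nrow(peaklists))) {
      pk <- peaklists$peaks[[sp]]
      if (!nrow(pk)) next
      ext <- extract_envelope(pk, heavy, settings$ppm_tol,
                              settings$min_matched)
      if (is.null(ext) || sum(ext$matched) < 3) next
      rows[[length(rows) + 1]] <- tibble(
        sequence = pep, spectrum = peaklists$spectrum[sp],
        envelope = list(ext))
    }
  }
  if (!length(rows)) {
    return(tibble(sequence = character(), spectrum = character(),
                  envelope = list()))
  }
  dplyr::bind_rows(rows)
}

# Number of theoretical slots with any spectrum peak inside the tolerance.
n_slots_matched <- function(peaks, theoretical, ppm_tol) {
  sum(vapply(theoretical$mz, function(m) {
    any(abs(peaks$mz - m) <= m * ppm_tol * 1e-6)
  }, logical(1)))
}

#' Run the full quantification workflow and write the output tree
#'
#' Runs [quantify_pairs()], aggregates to peptide and protein level, and
#' writes one folder per protein accession (per-peptide q tables and a
#' q-plot data file) plus flat summary tables and a run manifest with
#' filter-funnel counts.
#'
#' @inheritParams quantify_pairs
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with `measurements`, `peptides`, `proteins`,
#'   and `manifest`.
#' @export
run_quantify <- function(library, peaklists, proteins, out_dir,
                         settings = default_settings(),
                         gel_model = gel_model_log(),
                         id_schedule = schedule_48(),
                         quant_schedule = schedule_192()) {
  meas <- quantify_pairs(library, peaklists, proteins, settings,
                         gel_model, id_schedule, quant_schedule)
  pep <- aggregate_peptides(meas)
  prot <- aggregate_proteins(pep)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(meas, file.path(out_dir, "measurements.tsv"))
  readr::write_tsv(pep, file.path(out_dir, "peptides.tsv"))
  readr::write_tsv(prot, file.path(out_dir, "proteins.tsv"))
  acc_meas <- dplyr::filter(meas, .data$accepted)
  for (acc in unique(unlist(strsplit(acc_meas$accessions, ";")))) {
    adir <- file.path(out_dir, acc)
    dir.create(adir, showWarnings = FALSE)
    hits <- acc_meas[vapply(strsplit(acc_meas$accessions, ";"),
                            function(a) acc %in% a, logical(1)), ]
    for (pp in unique(hits$peptide)) {
      readr::write_tsv(hits[hits$peptide == pp, ],
                       file.path(adir, paste0(pp, ".tsv")))
    }
    readr::write_tsv(
      dplyr::select(hits, "peptide", "spectrum", "q"),
      file.path(adir, "qplot.tsv"))
  }
  quality_pass <- sum(!isFALSE_v(meas$pass_light) &
                        !isFALSE_v(meas$pass_heavy))
  manifest <- list(
    tool = paste0("n15quant ",
                  as.character(utils::packageVersion("n15quant"))),
    settings = settings[setdiff(names(settings), "multimers")],
    multimers = as.integer(settings$multimers),
    counts = list(
      spectra = nrow(peaklists),
      library_peptides = nrow(library),
      envelope_matches = nrow(meas),
      pass_quality = quality_pass,
      pass_position = sum(meas$gel_ok & meas$elution_ok),
      accepted = sum(meas$accepted),
      peptides_quantified = nrow(pep),
      proteins_quantified = nrow(prot)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(measurements = meas, peptides = pep, proteins = prot,
                 manifest = manifest))
}

isFALSE_v <- function(x) !is.na(x) & !x
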