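# Envelope quality control, heavy-fraction (q-value) computation, labeling
# efficiency estimation, positional consistency filters, and aggregation to
# peptide- and protein-level summaries.

# Bounded adjacent-pair ratio r = I[i+1] / (I[i] + I[i+1]) for each pair of
# consecutive filled slots; the envelope shape statistic. Scale-free, so a
# uniform intensity scaling leaves it unchanged.
adjacent_ratios <- function(intensity, matched = !is.na(intensity)) {
  n <- length(intensity)
  i <- which(matched[-n] & matched[-1])
  if (!length(i)) return(tibble(slot = integer(), r = numeric()))
  tibble(slot = i, r = intensity[i + 1] / (intensity[i] + intensity[i + 1]))
}

#' Envelope shape quality test
#'
#' Compares an extracted experimental envelope against its theoretical
#' counterpart by the bounded adjacent-pair ratio `r = I[i+1]/(I[i] +
#' I[i+1])`, computed for every pair of consecutive matched slots. The
#' envelope passes when every `|r_exp - r_theo|` is at most `threshold`.
#' This removes matches whose mass is right but whose amino-acid
#' composition (hence envelope shape) is wrong, and spectra with
#' overlapping signals.
#'
#' @param envelope Extraction result from [extract_envelope()].
#' @param threshold Maximum tolerated ratio difference (default 0.05).
#' @return A list of class `n15_quality`: `differences` (tibble `slot`,
#'   `r_exp`, `r_theo`, `diff`), `max_diff`, `pass`, `threshold`.
#' @export
envelope_quality <- function(envelope, threshold = 0.05) {
  stopifnot(threshold > 0)
  r_exp <- adjacent_ratios(envelope$intensity_obs, envelope$matched)
  if (nrow(r_exp) < 1) {
    abort("Fewer than 2 adjacent matched slots; envelope is untestable")
  }
  r_theo <- adjacent_ratios(envelope$intensity_theo,
                            envelope$matched)
  diffs <- dplyr::inner_join(
    dplyr::rename(r_exp, r_exp = "r"),
    dplyr::rename(r_theo, r_theo = "r"),
    by = "slot") |>
    dplyr::mutate(diff = abs(.data$r_exp - .data$r_theo))
  structure(list(differences = diffs,
                 max_diff = max(diffs$diff),
                 pass = all(diffs$diff <= threshold),
                 threshold = threshold),
            class = "n15_quality")
}

#' @export
print.n15_quality <- function(x, ...) {
  cat(sprintf("Envelope quality: %s (max |r_exp - r_theo| = %.4f, threshold %.3f)\n",
              if (x$pass) "PASS" else "FAIL", x$max_diff, x$threshold))
  invisible(x)
}

#' Heavy-fraction q-value
#'
#' The fraction of the summed pair signal contributed by the heavy
#' (15N-labeled) envelope: `q = heavy / (light + heavy)`. A q of 0.5 means
#' equal abundance in the two samples; q of 0.8 means the heavy sample has
#' 4x the abundance (fold = q / (1 - q)).
#'
#' @param light_sum,heavy_sum Summed matched-slot intensities of the light
#'   and heavy envelopes; non-negative, not both zero.
#' @return The q-value in \[0, 1\].
#' @export
#' @examples
#' q_value(20, 80)          # 0.8
#' q_fold(q_value(20, 80))  # 4
q_value <- function(light_sum, heavy_sum) {
  stopifnot(all(light_sum >= 0), all(heavy_sum >= 0))
  total <- light_sum + heavy_sum
  if (any(total <= 0)) abort("Both envelope sums are zero")
  heavy_sum / total
}

#' @rdname q_value
#' @param q A q-value.
#' @return `q_fold()`: the heavy:light abundance ratio `q / (1 - q)`
#'   (`Inf` at q = 1).
#' @export
q_fold <- function(q) ifelse(q >= 1, Inf, q / (1 - q))

#' Estimate 15N labeling efficiency by grid search
#'
#' Scans candidate enrichments and, for each, recomputes every peptide's
#' theoretical heavy envelope and accumulates the squared adjacent-ratio
#' differences against the supplied experimental envelopes (the same `r`
#' statistic as [envelope_quality()]). The grid value minimizing the mean
#' squared difference over comparable adjacent pairs is the
#' labeling-efficiency estimate; candidate enrichments whose envelope
#' window shares no slots with the observations score no fit.
#'
#' @param envelopes Tibble with one row per experimental heavy envelope:
#'   column `sequence` (peptide) and list-column `envelope` holding
#'   [extract_envelope()] results (at least 3 matched slots each).
#' @param grid_lo,grid_hi,step Search grid over the 15N fraction; defaults
#'   scan 0.90 to 1.00 in 0.001 steps.
#' @param carbamidomethyl Fixed cysteine modification for compositions.
#' @param max_peaks Envelope truncation passed to [isotope_envelope()].
#' @return An object of class `n15_enrichment_fit` with the estimate, the
#'   full fit profile, and a `boundary` flag set when the optimum sits on a
#'   grid edge (poor fit; e.g. unlabeled input pins to `grid_lo`).
#' @export
estimate_enrichment <- function(envelopes, grid_lo = 0.90, grid_hi = 1.00,
                                step = 0.001, carbamidomethyl = TRUE,
                                max_peaks = 8) {
  if (is.null(envelopes) || nrow(envelopes) < 1) {
    abort("No envelopes supplied for enrichment estimation")
  }
  keep <- vapply(envelopes$envelope,
                 function(e) sum(e$matched) >= 3, logical(1))
  if (!any(keep)) abort("No envelope has >= 3 matched slots")
  envelopes <- envelopes[keep, ]
  grid <- seq(grid_lo, grid_hi, by = step)
  comps <- lapply(unique(envelopes$sequence), composition_of,
                  carbamidomethyl = carbamidomethyl)
  names(comps) <- unique(envelopes$sequence)
  obs_ratios <- lapply(envelopes$envelope, function(e) {
    list(r = adjacent_ratios(e$intensity_obs, e$matched),
         nominal = e$nominal, matched = e$matched)
  })
  sse <- vapply(grid, function(p) {
    # the full candidate distribution (no window truncation), so every
    # observed slot is scored at every candidate enrichment; slots the
    # candidate cannot populate count as zero intensity, penalizing it
    theo <- lapply(comps, function(cc) {
      isotope_envelope(cc, enrichment = p, max_peaks = cc[["N"]] + 32)
    })
    total <- 0
    n_pairs <- 0L
    for (i in seq_len(nrow(envelopes))) {
      ob <- obs_ratios[[i]]
      tt <- theo[[envelopes$sequence[i]]]
      # align by extra-neutron index, shared across all enrichments
      theo_int <- tt$intensity[match(ob$nominal, tt$nominal)]
      theo_int[is.na(theo_int)] <- 0
      r_theo <- adjacent_ratios(theo_int, ob$matched)
      joined <- dplyr::inner_join(ob$r, r_theo, by = "slot",
                                  suffix = c("_exp", "_theo"))
      joined <- joined[is.finite(joined$r_theo), ]
      total <- total + sum((joined$r_exp - joined$r_theo)^2)
      n_pairs <- n_pairs + nrow(joined)
    }
    # nothing comparable at this enrichment (e.g. unlabeled input at full
    # enrichment): no fit
    if (n_pairs == 0L) Inf else total / n_pairs
  }, numeric(1))
  best <- which.min(sse)
  structure(list(estimate = grid[best],
                 profile = tibble(enrichment = grid, sse = sse),
                 boundary = best == 1L || best == length(grid) ||
                   !is.finite(sse[best]),
                 n_envelopes = nrow(envelopes)),
            class = "n15_enrichment_fit")
}

#' @export
print.n15_enrichment_fit <- function(x, ...) {
  cat(sprintf("15N labeling efficiency: %.3f (%d envelopes%s)\n",
              x$estimate, x$n_envelopes,
              if (x$boundary) "; WARNING: estimate on grid boundary" else ""))
  invisible(x)
}

#' Gel model: segment index to molecular-weight window
#'
#' Maps each excised gel segment to the molecular-weight interval (kDa) of
#' proteins banding there. Migration distance is roughly linear in log(MW),
#' so the default model spaces segment boundaries geometrically, segment 0
#' holding the largest proteins.
#'
#' @param n_segments Number of excised segments (default 36).
#' @param mw_hi,mw_lo Molecular-weight range covered (kDa), top to bottom of
#'   the gel.
#' @return A tibble with columns `segment`, `mw_lo`, `mw_hi`.
#' @export
gel_model_log <- function(n_segments = 36, mw_hi = 250, mw_lo = 10) {
  bounds <- exp(seq(log(mw_hi), log(mw_lo), length.out = n_segments + 1))
  tibble(segment = seq_len(n_segments) - 1L,
         mw_lo = bounds[-1], mw_hi = bounds[-(n_segments + 1)])
}

# Segment whose MW window contains `mw` (kDa); clamped at the gel ends.
gel_segment_for_mass <- function(gel_model, mw) {
  vapply(mw, function(m) {
    hit <- which(gel_model$mw_lo <= m & m <= gel_model$mw_hi)
    if (length(hit)) return(gel_model$segment[hit[1]])
    if (m > max(gel_model$mw_hi)) return(gel_model$segment[1])
    gel_model$segment[nrow(gel_model)]
  }, integer(1))
}

#' Positional consistency filters
#'
#' The two false-positive criteria for a peptide-pair match: (1) the
#' quantification spectrum must come from a gel segment next to the segment
#' of the MS/MS identification, and that segment's molecular-weight window
#' must contain the intact protein mass for some oligomeric state in
#' `multimers` (membrane proteins such as PIPs band both as ~30 kDa
#' monomers and ~60 kDa dimers); (2) the peptide must elute at a similar
#' LC position in the identification and quantification runs.
#'
#' @param quant_segment,quant_fraction Gel segment and LC fraction of the
#'   quantification spectrum.
#' @param id_segment,id_fraction Gel segment and LC fraction of the MS/MS
#'   identification.
#' @param quant_schedule,id_schedule [fraction_schedule()]s of the two runs.
#' @param protein_mass_kda Intact protein mass(es) in kDa; for a shared
#'   peptide pass all parents (any parent passing suffices).
#' @param gel_model Segment-to-MW map from [gel_model_log()].
#' @param elution_tol_min Allowed mid-fraction retention-time difference
#'   (minutes; default 1.5).
#' @param multimers Oligomeric states considered when checking the MW
#'   window (default monomer and dimer).
#' @param segment_neighborhood Allowed segment distance between ID and
#'   quantification spectra (default 1).
#' @return A list with logicals `gel_ok` and `elution_ok`.
#' @export
positional_filters <- function(quant_segment, quant_fraction,
                               id_segment, id_fraction,
                               quant_schedule = schedule_192(),
                               id_schedule = schedule_48(),
                               protein_mass_kda,
                               gel_model = gel_model_log(),
                               elution_tol_min = 1.5,
                               multimers = c(1, 2),
                               segment_neighborhood = 1) {
  if (!quant_segment %in% gel_model$segment) {
    abort(sprintf("Gel segment %d outside gel model", quant_segment))
  }
  seg <- gel_model[gel_model$segment == quant_segment, ]
  mw_ok <- any(vapply(protein_mass_kda, function(m) {
    any(seg$mw_lo <= multimers * m & multimers * m <= seg$mw_hi)
  }, logical(1)))
  gel_ok <- abs(quant_segment - id_segment) <= segment_neighborhood && mw_ok
  dt <- abs(fraction_time(quant_schedule, quant_fraction) -
              fraction_time(id_schedule, id_fraction))
  list(gel_ok = gel_ok, elution_ok = dt <= elution_tol_min)
}

#' Aggregate pair measurements to peptide level
#'
#' Keeps only measurements that passed both envelope-quality verdicts, both
#' positional filters, and are free of light/heavy envelope overlap, then
#' summarises each peptide over its accepted spectra.
#'
#' @param measurements Measurement tibble from [quantify_pairs()].
#' @return A tibble with one row per peptide: `peptide`, `accessions`,
#'   `unique`, `mean_q`, `sd_q` (0 when a single spectrum), `n_spectra`,
#'   `uncertain` (mean q outside \[0.2, 0.8\]).
#' @export
aggregate_peptides <- function(measurements) {
  acc <- dplyr::filter(measurements, .data$accepted)
  acc |>
    dplyr::group_by(.data$peptide, .data$accessions, .data$unique) |>
    dplyr::summarise(
      mean_q = mean(.data$q),
      sd_q = ifelse(dplyr::n() > 1, sd(.data$q), 0),
      n_spectra = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(uncertain = .data$mean_q > 0.8 | .data$mean_q < 0.2) |>
    dplyr::arrange(.data$accessions, .data$peptide)
}

#' Aggregate peptide summaries to protein level
#'
#' Only unique peptides quantify individual proteins: the protein q is the
#' mean of its unique-peptide mean q-values, the SD is taken over those
#' peptide means (for a single unique peptide the peptide's own
#' across-spectrum SD is reported), and the spectrum count sums over
#' peptides.
#'
#' @param peptide_quant Output of [aggregate_peptides()].
#' @return A tibble with one row per protein: `accession`, `mean_q`, `sd_q`,
#'   `n_peptides`, `n_spectra`.
#' @export
aggregate_proteins <- function(peptide_quant) {
  uq <- dplyr::filter(peptide_quant, .data$unique)
  uq |>
    dplyr::group_by(accession = .data$accessions) |>
    dplyr::summarise(
      protein_q = mean(.data$mean_q),
      protein_sd = ifelse(dplyr::n() > 1, sd(.data$mean_q), .data$sd_q[1]),
      n_peptides = dplyr::n(),
      n_spectra = sum(.data$n_spectra),
      .groups = "drop") |>
    dplyr::rename(mean_q = "protein_q", sd_q = "protein_sd") |>
    dplyr::arrange(.data$accession)
}

#' Default analysis settings
#'
#' All tunable parameters of the pipeline with their defaults: 30 ppm mass
#' tolerance, 0.05 envelope-ratio threshold, 0.982 labeling enrichment,
#' 0.90-1.00 enrichment grid at 0.001, 1.5 min elution tolerance, +-1 gel
#' segment with monomer/dimer MW windows, q uncertainty bounds 0.2/0.8,
#' trypsin with 1 missed cleavage, carbamidomethyl fixed, peptide length
#' 5-35, 8 envelope peaks, 3 matched slots minimum.
#'
#' @return A named list of settings.
#' @export
default_settings <- function() {
  list(ppm_tol = 30,
       ratio_threshold = 0.05,
       enrichment = 0.982,
       natural_n15 = NATURAL_N15,
       grid_lo = 0.90, grid_hi = 1.00, grid_step = 0.001,
       elution_tol_min = 1.5,
       min_matched = 3,
       max_peaks = 8,
       multimers = c(1, 2),
       segment_neighborhood = 1,
       uncertain_lo = 0.2, uncertain_hi = 0.8,
       carbamidomethyl = TRUE,
       max_missed = 1,
       min_length = 5, max_length = 35,
       label_swap = FALSE)
}

#' Read or write a settings file (YAML key-value)
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path Settings file path.
#' @return `read_settings()`: validated settings list.
#' @export
read_settings <- function(path) {
  vals <- yaml::read_yaml(path)
  defaults <- default_settings()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown settings: ", paste(unknown, collapse = ", ")))
  }
  out <- utils::modifyList(defaults, vals)
  validate_settings(out)
  out
}

#' @rdname read_settings
#' @param settings Settings list.
#' @export
write_settings <- function(settings, path) {
  validate_settings(settings)
  yaml::write_yaml(settings, path)
  invisible(path)
}

validate_settings <- function(s) {
  stopifnot(s$ppm_tol > 0, s$ratio_threshold > 0,
            s$enrichment >= 0, s$enrichment <= 1,
            s$grid_lo >= 0, s$grid_hi <= 1, s$grid_lo < s$grid_hi,
            s$grid_step > 0, s$elution_tol_min >= 0,
            s$min_matched >= 2, s$max_peaks >= 2,
            all(s$multimers >= 1), s$segment_neighborhood >= 0,
            s$uncertain_lo < s$uncertain_hi,
            s$max_missed >= 0, s$min_length >= 1,
            s$min_length <= s$max_length)
  invisible(s)
}
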