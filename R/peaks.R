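# Centroided peak-list I/O and extraction of experimental envelopes around
# theoretical target masses. The canonical on-disk dialect is one TSV file
# per spectrum ("m/z<TAB>intensity" lines) with a '#'-prefixed metadata
# header; a minimal MGF-like container is accepted for interoperability.

#' LC fraction-collection schedule
#'
#' @param n_fractions Number of MALDI spots collected.
#' @param start Collection start time (minutes into the gradient).
#' @param interval Collection interval per spot (minutes).
#' @return A `fraction_schedule` list.
#' @export
#' @examples
#' fraction_schedule(48, start = 28, interval = 0.7)
fraction_schedule <- function(n_fractions, start, interval) {
  stopifnot(n_fractions >= 1, interval > 0)
  structure(list(n_fractions = as.integer(n_fractions),
                 start = start, interval = interval),
            class = "fraction_schedule")
}

#' Standard schedules: 48 spots at 0.7 min (identification runs) and 192
#' spots at 0.15 min (mixed light/heavy quantification runs), both starting
#' at 28 min into the gradient.
#' @rdname fraction_schedule
#' @export
schedule_48 <- function() fraction_schedule(48, 28, 0.7)

#' @rdname fraction_schedule
#' @export
schedule_192 <- function() fraction_schedule(192, 28, 0.15)

#' Mid-fraction retention time
#'
#' Maps a fraction index to the midpoint of its collection window, allowing
#' elution positions to be compared across runs collected on different
#' schedules.
#'
#' @param schedule A [fraction_schedule()].
#' @param fraction_index 0-based fraction index.
#' @return Retention time in minutes.
#' @export
#' @examples
#' fraction_time(schedule_48(), 0)   # 28.35
#' fraction_time(schedule_192(), 0)  # 28.075
fraction_time <- function(schedule, fraction_index) {
  stopifnot(inherits(schedule, "fraction_schedule"))
  if (any(fraction_index < 0 | fraction_index >= schedule$n_fractions)) {
    abort("Fraction index outside schedule")
  }
  schedule$start + (fraction_index + 0.5) * schedule$interval
}

#' Read centroided peak lists
#'
#' Reads either a directory of per-spectrum TSV files (the canonical
#' dialect) or a single `.mgf` file. Peaks are sorted by m/z on load so
#' downstream results do not depend on file order.
#'
#' @param source Directory of `.tsv` spectrum files, a single `.tsv` file,
#'   or an `.mgf` file.
#' @return A tibble with one row per spectrum: `spectrum`, `run`,
#'   `lc_fraction`, `gel_segment`, and a `peaks` list-column of tibbles
#'   (`mz`, `intensity`).
#' @export
read_peaklists <- function(source) {
  if (dir.exists(source)) {
    files <- list.files(source, pattern = "\\.tsv$", full.names = TRUE,
                        recursive = TRUE)
    if (!length(files)) abort(paste0("No .tsv peak lists under ", source))
    return(dplyr::bind_rows(lapply(sort(files), read_peaklist_tsv)))
  }
  if (!file.exists(source)) abort(paste0("No such peak-list source: ", source))
  if (grepl("\\.mgf$", source, ignore.case = TRUE)) {
    return(read_peaklist_mgf(source))
  }
  read_peaklist_tsv(source)
}

read_peaklist_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grepl("^#", lines)
  meta <- lines[meta_idx]
  kv <- strsplit(sub("^#\\s*", "", meta), "\\s*:\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ":"), "")
  need <- c("spectrum", "run", "lc_fraction", "gel_segment")
  if (!all(need %in% keys)) {
    abort(sprintf("Peak list %s: missing metadata %s", path,
                  paste(setdiff(need, keys), collapse = ", ")))
  }
  meta <- setNames(vals, keys)
  body <- lines[!meta_idx & nzchar(lines)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    ok <- lengths(parts) == 2
    if (any(!ok)) {
      abort(sprintf("Peak list %s: malformed line(s) %s", path,
                    paste(which(!meta_idx & nzchar(lines))[!ok],
                          collapse = ", ")))
    }
    mz <- as.numeric(vapply(parts, `[`, "", 1))
    intensity <- as.numeric(vapply(parts, `[`, "", 2))
    if (anyNA(mz) || anyNA(intensity)) {
      abort(paste0("Peak list ", path, ": non-numeric peak values"))
    }
    ord <- order(mz)
    peaks <- tibble(mz = mz[ord], intensity = intensity[ord])
  } else {
    peaks <- tibble(mz = numeric(), intensity = numeric())
  }
  tibble(spectrum = meta[["spectrum"]], run = meta[["run"]],
         lc_fraction = as.integer(meta[["lc_fraction"]]),
         gel_segment = as.integer(meta[["gel_segment"]]),
         peaks = list(peaks))
}

# MGF-like: BEGIN IONS / END IONS blocks; TITLE carries
# "spectrum=<id> run=<id> lc_fraction=<i> gel_segment=<i>" tags.
read_peaklist_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end) || any(end < begin)) {
    abort(paste0("Unbalanced BEGIN/END IONS in ", path))
  }
  out <- purrr::map2_dfr(begin, end, function(b, e) {
    block <- lines[(b + 1):(e - 1)]
    title <- sub("^TITLE=", "", block[grepl("^TITLE=", block)][1])
    if (is.na(title)) abort(paste0("MGF block without TITLE in ", path))
    tag <- function(name) {
      m <- regmatches(title, regexec(paste0(name, "=(\\S+)"), title))[[1]]
      if (length(m) < 2) {
        abort(sprintf("MGF TITLE lacks %s tag (spectrum near line %d)",
                      name, b))
      }
      m[2]
    }
    body <- block[!grepl("^[A-Z]+=", block) & nzchar(block)]
    mz <- as.numeric(sub("\\s.*$", "", body))
    intensity <- as.numeric(sub("^\\S+\\s+", "", body))
    ord <- order(mz)
    tibble(spectrum = tag("spectrum"), run = tag("run"),
           lc_fraction = as.integer(tag("lc_fraction")),
           gel_segment = as.integer(tag("gel_segment")),
           peaks = list(tibble(mz = mz[ord], intensity = intensity[ord])))
  })
  out
}

#' Write peak lists in the canonical TSV dialect
#'
#' One file per spectrum (named `<spectrum>.tsv`) under `dir`; round-trips
#' bit-exactly through [read_peaklists()].
#'
#' @param peaklists Tibble as produced by [read_peaklists()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_peaklists <- function(peaklists, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(peaklists))) {
    row <- peaklists[i, ]
    path <- file.path(dir, paste0(row$spectrum, ".tsv"))
    hdr <- sprintf("# %s: %s",
                   c("spectrum", "run", "lc_fraction", "gel_segment"),
                   c(row$spectrum, row$run, row$lc_fraction, row$gel_segment))
    pk <- row$peaks[[1]]
    body <- sprintf("%.17g\t%.17g", pk$mz, pk$intensity)
    writeLines(c(hdr, body), path)
  }
  invisible(dir)
}

#' Extract an experimental envelope around a theoretical one
#'
#' For every theoretical peak slot, the nearest spectrum peak within
#' `ppm_tol` is taken (ties broken toward the more intense peak). The match
#' is accepted only if at least `min_matched` consecutive slots, including
#' the theoretically most intense slot, are filled; otherwise `NULL` is
#' returned (absence is a valid outcome).
#'
#' @param peaks Tibble with `mz` and `intensity` (one spectrum), sorted or
#'   not.
#' @param theoretical An `n15_envelope` from [isotope_envelope()].
#' @param ppm_tol Matching tolerance in parts per million (default 30, the
#'   usual MALDI-TOF search tolerance after internal calibration).
#' @param min_matched Minimum run of consecutive filled slots containing the
#'   apex slot (default 3; the envelope-shape test needs >= 2 adjacent
#'   pairs).
#' @return A tibble with one row per theoretical slot: `slot`, `mz_theo`,
#'   `intensity_theo`, `mz_obs`, `intensity_obs`, `matched`; or `NULL`.
#' @export
extract_envelope <- function(peaks, theoretical, ppm_tol = 30,
                             min_matched = 3) {
  stopifnot(ppm_tol > 0)
  mz_theo <- theoretical$mz
  n_slot <- length(mz_theo)
  mz_obs <- rep(NA_real_, n_slot)
  int_obs <- rep(NA_real_, n_slot)
  if (nrow(peaks)) {
    for (s in seq_len(n_slot)) {
      tol <- mz_theo[s] * ppm_tol * 1e-6
      d <- abs(peaks$mz - mz_theo[s])
      inside <- which(d <= tol)
      if (!length(inside)) next
      best <- inside[order(d[inside], -peaks$intensity[inside])]
      # ties (equal distance within numerical noise) -> higher intensity
      dmin <- d[best[1]]
      cand <- best[abs(d[best] - dmin) <= 1e-9 * mz_theo[s]]
      pick <- cand[which.max(peaks$intensity[cand])]
      mz_obs[s] <- peaks$mz[pick]
      int_obs[s] <- peaks$intensity[pick]
    }
  }
  matched <- !is.na(mz_obs)
  apex <- which.max(theoretical$intensity)
  if (!matched[apex]) return(NULL)
  # length of the consecutive matched run through the apex slot
  lo <- apex
  while (lo > 1 && matched[lo - 1]) lo <- lo - 1
  hi <- apex
  while (hi < n_slot && matched[hi + 1]) hi <- hi + 1
  if (hi - lo + 1 < min_matched) return(NULL)
  tibble(slot = seq_len(n_slot),
         nominal = theoretical$nominal,
         mz_theo = mz_theo,
         intensity_theo = theoretical$intensity,
         mz_obs = mz_obs,
         intensity_obs = int_obs,
         matched = matched)
}
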