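# In-silico tryptic digestion, peptide -> protein mapping, and unique/shared
# classification across isoform families. Uniqueness is exact-substring based:
# exhaustive digestion of the family replaces any manual sequence alignment.

#' Read a protein FASTA file
#'
#' @param path FASTA file of amino-acid sequences. The accession is the first
#'   whitespace-delimited token of each header; the remainder is kept as the
#'   annotation.
#' @return A tibble with columns `accession`, `sequence`, `annotation`.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort(paste0("No sequences in FASTA: ", path))
  headers <- names(seqs)
  accession <- sub("\\s.*$", "", headers)
  annotation <- ifelse(grepl("\\s", headers),
                       sub("^\\S+\\s+", "", headers), "")
  tibble(accession = accession,
         sequence = unname(toupper(as.character(seqs))),
         annotation = annotation)
}

#' Write a protein table as FASTA
#'
#' @param proteins Tibble with `accession`, `sequence` and optionally
#'   `annotation` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  ann <- if ("annotation" %in% names(proteins)) proteins$annotation else ""
  hdr <- ifelse(nzchar(ann), paste(proteins$accession, ann),
                proteins$accession)
  seqs <- Biostrings::AAStringSet(setNames(proteins$sequence, hdr))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Tryptic digestion of one protein sequence
#'
#' Cleaves after K or R, suppressed when the following residue is proline
#' (the classic trypsin rule; disable with `no_p_rule = TRUE`), and
#' enumerates all peptides with up to `max_missed` internal uncleaved sites.
#'
#' @param sequence Amino-acid string.
#' @param max_missed Maximum number of missed cleavages (>= 0). One missed
#'   cleavage is the usual search-engine setting for gel-digested samples.
#' @param no_p_rule If `TRUE`, cleave after K/R even before proline.
#' @return A tibble with columns `peptide`, `start`, `end` (1-based,
#'   inclusive) and `missed` (internal uncleaved K/R sites).
#' @export
#' @examples
#' tryptic_digest("VGANKFPER", max_missed = 1)
tryptic_digest <- function(sequence, max_missed = 1, no_p_rule = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence)) abort("Empty protein sequence")
  stopifnot(max_missed >= 0)
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  is_site <- res %in% c("K", "R")
  if (!no_p_rule && n > 1) {
    followed_by_p <- c(res[-1] == "P", FALSE)
    is_site <- is_site & !followed_by_p
  }
  is_site[n] <- FALSE  # a C-terminal K/R ends the last fragment anyway
  cuts <- c(0L, which(is_site), n)  # fragment boundaries
  n_frag <- length(cuts) - 1L
  out <- vector("list", 0L)
  for (i in seq_len(n_frag)) {
    for (m in 0:min(max_missed, n_frag - i)) {
      start <- cuts[i] + 1L
      end <- cuts[i + 1L + m]
      out[[length(out) + 1L]] <- list(
        peptide = substr(sequence, start, end),
        start = start, end = end, missed = m)
    }
  }
  dplyr::bind_rows(out)
}

#' Build a peptide-to-protein map from a protein collection
#'
#' Digests every protein and maps each peptide (within length bounds) to the
#' set of all proteins that produce it as a tryptic product. Accession lists
#' are sorted, so the map is deterministic and idempotent.
#'
#' @param proteins Tibble with `accession` and `sequence` columns;
#'   accessions must be unique.
#' @param max_missed Missed-cleavage limit passed to [tryptic_digest()].
#' @param min_length,max_length Peptide length bounds (residues). Defaults
#'   5-35 cover the mass range observable by MALDI-TOF.
#' @param carbamidomethyl Fixed cysteine modification used when computing
#'   masses downstream; recorded on the map attributes.
#' @return A tibble with columns `peptide`, `accessions` (semicolon-joined,
#'   sorted), `n_proteins`, `missed` (minimum missed-cleavage count over
#'   occurrences) and `unique` (logical, exactly one parent).
#' @export
build_peptide_map <- function(proteins, max_missed = 1,
                              min_length = 5, max_length = 35,
                              carbamidomethyl = TRUE) {
  stopifnot(nrow(proteins) >= 1)
  if (anyDuplicated(proteins$accession)) {
    abort("Duplicate accessions in protein collection")
  }
  digested <- purrr::map2_dfr(
    proteins$accession, proteins$sequence,
    function(acc, seq) {
      d <- tryptic_digest(seq, max_missed = max_missed)
      d$accession <- acc
      d
    })
  digested <- dplyr::filter(
    digested,
    nchar(.data$peptide) >= min_length,
    nchar(.data$peptide) <= max_length)
  map <- digested |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(
      accessions = paste(sort(unique(.data$accession)), collapse = ";"),
      n_proteins = dplyr::n_distinct(.data$accession),
      missed = min(.data$missed),
      .groups = "drop") |>
    dplyr::mutate(unique = .data$n_proteins == 1L) |>
    dplyr::arrange(.data$peptide)
  structure(map, carbamidomethyl = carbamidomethyl)
}

#' Classify peptide uniqueness within an isoform family
#'
#' Restricts a peptide map to a subset of accessions (an isoform family) and
#' re-derives the unique/shared partition within that subset. Because
#' pairing is mass-only downstream, leucine and isoleucine are isobaric;
#' with `il_equivalent = TRUE` peptides whose sequences coincide under I=L
#' are collapsed into one entry whose parent set is the union.
#'
#' @param peptide_map Output of [build_peptide_map()].
#' @param family Character vector of accessions (must all occur in the map);
#'   `NULL` keeps the whole collection.
#' @param il_equivalent Collapse I/L-isobaric peptides (default `FALSE` for
#'   sequence bookkeeping; enable for mass-faithful uniqueness).
#' @return A tibble with columns `peptide`, `accessions`, `n_proteins`,
#'   `unique`, and `il_collapsed` (logical: entry merged distinct sequences).
#' @export
classify_uniqueness <- function(peptide_map, family = NULL,
                                il_equivalent = FALSE) {
  all_acc <- unique(unlist(strsplit(peptide_map$accessions, ";")))
  if (is.null(family)) family <- all_acc
  missing <- setdiff(family, all_acc)
  if (length(missing)) {
    abort(paste0("Accessions not in peptide map: ",
                 paste(missing, collapse = ", ")))
  }
  long <- peptide_map |>
    dplyr::select("peptide") |>
    dplyr::mutate(accession = strsplit(peptide_map$accessions, ";")) |>
    tidyr::unnest("accession") |>
    dplyr::filter(.data$accession %in% family)
  key <- if (il_equivalent) gsub("I", "L", long$peptide) else long$peptide
  long$key <- key
  long |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      il_collapsed = dplyr::n_distinct(.data$peptide) > 1L,
      accessions = paste(sort(unique(.data$accession)), collapse = ";"),
      n_proteins = dplyr::n_distinct(.data$accession),
      peptide = sort(unique(.data$peptide))[1],
      .groups = "drop") |>
    dplyr::mutate(unique = .data$n_proteins == 1L) |>
    dplyr::select("peptide", "accessions", "n_proteins", "unique",
                  "il_collapsed") |>
    dplyr::arrange(.data$peptide)
}

#' Write a peptide map as a tab-separated table
#'
#' @param peptide_map Output of [build_peptide_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_map <- function(peptide_map, path) {
  readr::write_tsv(peptide_map, path)
  invisible(path)
}
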