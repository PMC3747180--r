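# Peptide elemental composition, monoisotopic mass, and theoretical isotope
# envelopes at arbitrary 15N enrichment. Envelopes are aggregated on the
# unit-mass grid (one centroid per nominal mass), which is what a MALDI-TOF
# reflector resolves for peptides; fine isotopologue structure is not modeled.

#' Elemental composition of a peptide
#'
#' Sums the residue formulas of a peptide sequence plus one water (the
#' termini), optionally applying carbamidomethylation as a fixed modification
#' on every cysteine.
#'
#' @param sequence Uppercase amino-acid string using the 20 standard residue
#'   letters. Ambiguity/rare codes (B, J, O, U, X, Z) are rejected.
#' @param carbamidomethyl Apply the +C2H3NO fixed modification to every `C`
#'   residue (iodoacetamide alkylation), as is standard after gel digestion.
#' @return Named integer vector of atom counts over C, H, N, O, S.
#' @export
#' @examples
#' composition_of("DVEGPEGFQTR")
composition_of <- function(sequence, carbamidomethyl = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence)) abort("Peptide sequence is empty")
  res <- strsplit(sequence, "")[[1]]
  mat <- get_residues()
  bad <- which(!res %in% rownames(mat))
  if (length(bad)) {
    abort(sprintf("Unknown residue '%s' at position %d in '%s'",
                  res[bad[1]], bad[1], sequence))
  }
  counts <- colSums(mat[res, , drop = FALSE])
  counts <- counts + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # + H2O termini
  if (carbamidomethyl) {
    n_cys <- sum(res == "C")
    counts <- counts + n_cys * CARBAMIDOMETHYL_DELTA
  }
  storage.mode(counts) <- "integer"
  counts
}

check_composition <- function(composition) {
  if (is.null(names(composition)) ||
      !all(names(composition) %in% elements_tracked)) {
    abort("Composition must be a named vector over elements C, H, N, O, S")
  }
  if (any(composition < 0)) abort("Negative atom count in composition")
  full <- setNames(integer(length(elements_tracked)), elements_tracked)
  full[names(composition)] <- as.integer(composition)
  full
}

#' Monoisotopic mass of an elemental composition
#'
#' @param composition Named atom-count vector as returned by
#'   [composition_of()].
#' @return Neutral monoisotopic mass in Da (lightest isotope of each element).
#' @export
#' @examples
#' monoisotopic_mass(composition_of("DRVYIHPF"))
monoisotopic_mass <- function(composition) {
  composition <- check_composition(composition)
  iso <- isotope_list()
  sum(vapply(elements_tracked,
             function(el) composition[[el]] * iso[[el]]$mass[1],
             numeric(1)))
}

#' Singly-protonated m/z
#'
#' MALDI produces predominantly singly protonated ions; m/z of \[M+H\]+ is
#' the neutral mass plus one proton.
#'
#' @param neutral_mass Neutral monoisotopic (or centroid) mass in Da.
#' @return m/z at charge 1.
#' @export
mz_protonated <- function(neutral_mass) neutral_mass + PROTON_MASS

#' Heavy-envelope mass shift
#'
#' Mass separation between the fully labeled (all-15N) monoisotopic peak and
#' the unlabeled one: the nitrogen count times m(15N) - m(14N). Used to
#' position the search window for the heavy partner of a peptide pair. At
#' partial enrichment intensity moves to lighter isotopologues, but the
#' full-enrichment shift still brackets the heavy envelope from above.
#'
#' @param composition Named atom-count vector; must contain nitrogen.
#' @return Mass shift in Da at full enrichment.
#' @export
#' @examples
#' heavy_mass_shift(composition_of("DVEGPEGFQTR"))  # 15 N -> ~14.96 Da
heavy_mass_shift <- function(composition) {
  composition <- check_composition(composition)
  if (composition[["N"]] < 1) {
    abort("Composition has no nitrogen; not a peptide")
  }
  composition[["N"]] * N15_SHIFT
}

# Single-atom distribution over nominal-mass offsets for one element:
# list(p = probabilities per extra-neutron bin, pm = p * mass per bin).
atom_distribution <- function(element, n15 = NULL) {
  iso <- isotope_list()[[element]]
  mass <- iso$mass
  ab <- iso$abundance
  if (element == "N" && !is.null(n15)) ab <- c(1 - n15, n15)
  offset <- round(mass - mass[1])
  p <- numeric(max(offset) + 1)
  pm <- numeric(max(offset) + 1)
  for (i in seq_along(mass)) {
    p[offset[i] + 1] <- p[offset[i] + 1] + ab[i]
    pm[offset[i] + 1] <- pm[offset[i] + 1] + ab[i] * mass[i]
  }
  list(p = p, pm = pm)
}

# Convolve two (p, pm) bin distributions, keeping at most keep bins.
convolve_dist <- function(a, b, keep) {
  na <- length(a$p); nb <- length(b$p)
  n <- min(na + nb - 1, keep)
  p <- numeric(n); pm <- numeric(n)
  for (i in seq_len(na)) {
    jmax <- min(nb, n - i + 1)
    if (jmax < 1) break
    idx <- i:(i + jmax - 1)
    p[idx] <- p[idx] + a$p[i] * b$p[1:jmax]
    pm[idx] <- pm[idx] + a$pm[i] * b$p[1:jmax] + a$p[i] * b$pm[1:jmax]
  }
  list(p = p, pm = pm)
}

# n-fold self-convolution by binary exponentiation.
power_dist <- function(d, n, keep) {
  result <- NULL
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- if (is.null(result)) d else convolve_dist(result, d, keep)
    }
    n <- n %/% 2
    if (n > 0) d <- convolve_dist(d, d, keep)
  }
  if (is.null(result)) list(p = 1, pm = 0) else result
}

#' Theoretical isotope envelope at a given 15N enrichment
#'
#' Computes the isotopologue distribution of a peptide by per-element
#' binomial/multinomial expansion and cross-element convolution, with the
#' natural nitrogen isotope abundances replaced by `(1 - enrichment,
#' enrichment)`. Isotopologues are aggregated on the unit-mass grid: each
#' nominal-mass bin becomes one peak whose centroid m/z is the
#' abundance-weighted mean mass of its isotopologues (plus one proton). The
#' envelope is truncated to the most intense contiguous window of
#' `max_peaks` peaks and renormalized.
#'
#' @param composition Named atom-count vector from [composition_of()].
#' @param enrichment Fraction of nitrogen atoms that are 15N, in \[0, 1\].
#'   `NATURAL_N15` (0.00364) for unlabeled material; 0.982 was a typical
#'   labeling efficiency for hydroponically grown plants.
#' @param max_peaks Number of peaks retained; must be >= 2 (the envelope
#'   shape test needs at least one adjacent pair). Default 8 covers >99.9%
#'   of intensity for peptides under ~3 kDa.
#' @return A tibble of class `n15_envelope` with columns `mz` (\[M+H\]+ at
#'   charge 1, Da), `intensity` (fractions summing to 1 after truncation)
#'   and `nominal` (extra-neutron index relative to the all-light peak);
#'   attributes `enrichment` and `composition`.
#' @export
#' @examples
#' isotope_envelope(composition_of("DVEGPEGFQTR"), enrichment = 0.982)
isotope_envelope <- function(composition, enrichment = NATURAL_N15,
                             max_peaks = 8) {
  composition <- check_composition(composition)
  stopifnot(length(enrichment) == 1, enrichment >= 0, enrichment <= 1)
  if (max_peaks < 2) abort("max_peaks must be >= 2")
  # bins must reach the fully labeled region (N extra neutrons) plus the
  # C/H/O spread, whatever the truncation later keeps
  keep <- composition[["N"]] + max_peaks + 24L
  dist <- NULL
  for (el in elements_tracked) {
    n <- composition[[el]]
    if (n == 0) next
    d <- power_dist(atom_distribution(el, n15 = enrichment), n, keep)
    dist <- if (is.null(dist)) d else convolve_dist(dist, d, keep)
  }
  if (is.null(dist)) abort("Empty composition")
  total <- sum(dist$p)
  # pick the contiguous max_peaks window with the largest summed intensity
  p <- dist$p
  if (length(p) > max_peaks) {
    win <- vapply(seq_len(length(p) - max_peaks + 1),
                  function(i) sum(p[i:(i + max_peaks - 1)]), numeric(1))
    i0 <- which.max(win)
    idx <- i0:(i0 + max_peaks - 1)
  } else {
    idx <- seq_along(p)
  }
  idx <- idx[dist$p[idx] > 0]
  intensity <- dist$p[idx] / sum(dist$p[idx])
  centroid <- dist$pm[idx] / dist$p[idx]
  out <- tibble(
    mz = mz_protonated(centroid),
    intensity = intensity,
    nominal = idx - 1L
  )
  structure(out,
            class = c("n15_envelope", class(out)),
            enrichment = enrichment,
            composition = composition,
            total_intensity = total)
}

#' @export
print.n15_envelope <- function(x, ...) {
  cat(sprintf("Isotope envelope at %.4f 15N enrichment (%d peaks)\n",
              attr(x, "enrichment"), nrow(x)))
  NextMethod()
}
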