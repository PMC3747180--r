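# Shared-peptide arithmetic: a peptide present in several isoforms reports
# the abundance-weighted mean of their heavy fractions. Forward prediction,
# two-component inversion to an abundance ratio, and feasibility bounds for
# larger families. Equal ionization/detection efficiency of the shared
# peptide across isoforms is assumed throughout (flagged on every output).

#' Predict the q-value of a shared peptide
#'
#' A peptide shared by several isoforms mixes their signals: its q is the
#' abundance-weighted mean of the component q-values, `sum(w_i * q_i)`.
#'
#' @param weights Isoform abundance fractions (non-negative, summing to 1).
#' @param component_qs Per-isoform q-values in \[0, 1\], same length.
#' @return The predicted shared-peptide q-value.
#' @export
#' @examples
#' predict_shared_q(c(0.5, 0.5), c(0.60, 0.34))  # 0.47
predict_shared_q <- function(weights, component_qs) {
  if (length(weights) != length(component_qs)) {
    abort("weights and component_qs differ in length")
  }
  stopifnot(all(weights >= 0), abs(sum(weights) - 1) < 1e-9,
            all(component_qs >= 0), all(component_qs <= 1))
  sum(weights * component_qs)
}

#' Invert a two-isoform shared q to an abundance ratio
#'
#' Solves `q_shared = w1 * q1 + w2 * q2` with `w1 + w2 = 1` for the
#' abundance weights, giving `w1 = (q_shared - q2) / (q1 - q2)`, and
#' reports the component-2 : component-1 abundance ratio `w2 / w1`. When
#' the shared q lies outside `[min(q1, q2), max(q1, q2)]` no mixture
#' reproduces it; the result is flagged infeasible and the clamped boundary
#' solution is returned. A conditioning warning is raised when
#' `|q1 - q2| < 0.1`, where the inversion amplifies noise strongly.
#'
#' @param q_shared Observed q of the shared peptide.
#' @param q1,q2 Unique-peptide q-values of the two isoforms (must differ).
#' @return A list of class `n15_isoform_ratio`: `weights` (w1, w2), `ratio`
#'   (w2/w1), `ratio_rounded` (one significant figure, how such ratios are
#'   commonly communicated), `feasible`, `conditioning_warning`,
#'   `assumes_equal_response`.
#' @export
#' @examples
#' invert_two_component(0.39, 0.60, 0.34)  # ratio ~4.2
invert_two_component <- function(q_shared, q1, q2) {
  stopifnot(q_shared >= 0, q_shared <= 1)
  if (q1 == q2) abort("q1 = q2: mixture weights are unidentifiable")
  w1 <- (q_shared - q2) / (q1 - q2)
  feasible <- w1 >= 0 && w1 <= 1
  w1c <- min(max(w1, 0), 1)
  w2c <- 1 - w1c
  ratio <- if (w1c == 0) Inf else w2c / w1c
  structure(list(
    weights = c(w1 = w1c, w2 = w2c),
    ratio = ratio,
    ratio_rounded = signif(ratio, 1),
    feasible = feasible,
    conditioning_warning = abs(q1 - q2) < 0.1,
    assumes_equal_response = TRUE),
    class = "n15_isoform_ratio")
}

#' @export
print.n15_isoform_ratio <- function(x, ...) {
  cat(sprintf(
    "Isoform weights (w1, w2) = (%.3f, %.3f); ratio w2/w1 = %.3g (~%g)%s%s\n",
    x$weights[1], x$weights[2], x$ratio, x$ratio_rounded,
    if (!x$feasible) " [INFEASIBLE: clamped to boundary]" else "",
    if (x$conditioning_warning) " [poorly conditioned: |q1-q2| < 0.1]" else ""))
  invisible(x)
}

#' Feasibility bounds for a family-level shared peptide
#'
#' For a peptide shared by three or more isoforms no point estimate of the
#' weights exists; this reports what the shared q does constrain. With all
#' component q-values known, feasibility requires the shared q to lie
#' within their range. With exactly one unknown component, the feasible
#' interval of that component's abundance weight is returned (derived from
#' the mixture constraint with the unknown component's q free in \[0, 1\]).
#' In every case the shared q itself is the family-level aggregate, with
#' its heavy:light tissue ratio `q/(1-q)`.
#'
#' @param q_shared Observed q of the shared peptide.
#' @param component_qs Per-isoform q-values; `NA` for isoforms lacking a
#'   unique-peptide q.
#' @return A list: `feasible` (NA when undetermined), `known_range`,
#'   `n_unknown`, `unknown_weight_interval` (when exactly one unknown),
#'   `family_q`, `family_ratio`.
#' @export
family_bounds <- function(q_shared, component_qs) {
  stopifnot(length(component_qs) >= 3, q_shared >= 0, q_shared <= 1)
  known <- component_qs[!is.na(component_qs)]
  n_unknown <- sum(is.na(component_qs))
  known_range <- if (length(known)) range(known) else c(NA_real_, NA_real_)
  feasible <- NA
  interval <- NULL
  if (n_unknown == 0) {
    feasible <- q_shared >= known_range[1] && q_shared <= known_range[2]
  } else if (n_unknown == 1 && length(known) >= 1) {
    # weight w of the unknown component: with its q free in [0, 1], the
    # known components can contribute any value in
    # [(1-w)*min(known), (1-w)*max(known)], so w is feasible iff that
    # interval intersects [q_shared - w, q_shared].
    w <- seq(0, 1, by = 1e-4)
    lo <- (1 - w) * known_range[1]
    hi <- (1 - w) * known_range[2]
    ok <- lo <= q_shared & hi >= q_shared - w
    feasible <- any(ok)
    interval <- if (any(ok)) range(w[ok]) else NULL
  }
  list(feasible = feasible,
       known_range = known_range,
       n_unknown = n_unknown,
       unknown_weight_interval = interval,
       family_q = q_shared,
       family_ratio = q_fold(q_shared),
       assumes_equal_response = TRUE)
}

#' Isoform abundance-ratio table from quantification summaries
#'
#' Scans the peptide summary for peptides shared between exactly two
#' isoforms that both carry a unique-peptide protein q, and inverts each
#' shared q to an abundance ratio.
#'
#' @param peptide_quant Output of [aggregate_peptides()].
#' @param protein_quant Output of [aggregate_proteins()].
#' @return A tibble with one row per invertible shared peptide: `peptide`,
#'   `isoform1`, `isoform2`, `q_shared`, `q1`, `q2`, `ratio`
#'   (isoform2:isoform1), `ratio_rounded`, `feasible`,
#'   `conditioning_warning`.
#' @export
isoform_ratio_table <- function(peptide_quant, protein_quant) {
  shared <- dplyr::filter(peptide_quant, !.data$unique)
  rows <- list()
  for (i in seq_len(nrow(shared))) {
    acc <- strsplit(shared$accessions[i], ";")[[1]]
    if (length(acc) != 2) next
    qs <- protein_quant$mean_q[match(acc, protein_quant$accession)]
    if (anyNA(qs) || qs[1] == qs[2]) next
    inv <- invert_two_component(shared$mean_q[i], qs[1], qs[2])
    rows[[length(rows) + 1]] <- tibble(
      peptide = shared$peptide[i],
      isoform1 = acc[1], isoform2 = acc[2],
      q_shared = shared$mean_q[i], q1 = qs[1], q2 = qs[2],
      ratio = inv$ratio, ratio_rounded = inv$ratio_rounded,
      feasible = inv$feasible,
      conditioning_warning = inv$conditioning_warning)
  }
  if (!length(rows)) {
    return(tibble(peptide = character(), isoform1 = character(),
                  isoform2 = character(), q_shared = numeric(),
                  q1 = numeric(), q2 = numeric(), ratio = numeric(),
                  ratio_rounded = numeric(), feasible = logical(),
                  conditioning_warning = logical()))
  }
  dplyr::bind_rows(rows)
}
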