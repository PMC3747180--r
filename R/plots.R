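# Plotting and broom-style accessors for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the enrichment-fit profile
#'
#' @param x An `n15_enrichment_fit` from [estimate_enrichment()].
#' @param ... Unused.
#' @return A tibble with columns `enrichment` and `sse` (the fit profile).
#' @export
tidy.n15_enrichment_fit <- function(x, ...) x$profile

#' One-row summary of an enrichment fit
#'
#' @param x An `n15_enrichment_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `estimate`, `sse_min`, `n_envelopes`,
#'   `boundary`.
#' @export
glance.n15_enrichment_fit <- function(x, ...) {
  tibble(estimate = x$estimate,
         sse_min = min(x$profile$sse),
         n_envelopes = x$n_envelopes,
         boundary = x$boundary)
}

#' Plot an enrichment-fit profile
#'
#' Sum of squared adjacent-ratio differences against candidate 15N
#' enrichment, with the minimizing grid value marked.
#'
#' @param object An `n15_enrichment_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.n15_enrichment_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$enrichment, y = .data$sse)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$estimate, linetype = "dashed") +
    ggplot2::labs(x = "15N enrichment", y = "Summed squared ratio difference",
                  title = sprintf("Labeling efficiency estimate: %.3f",
                                  object$estimate)) +
    ggplot2::theme_minimal()
}

#' Plot a theoretical isotope envelope
#'
#' @param object An `n15_envelope` from [isotope_envelope()].
#' @param ... Unused.
#' @return A ggplot object (stick spectrum).
#' @export
autoplot.n15_envelope <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$mz, xend = .data$mz,
                               y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    ggplot2::labs(x = "m/z", y = "Relative intensity",
                  title = sprintf("Isotope envelope at %.4f 15N",
                                  attr(object, "enrichment"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' q-value dot plot per protein
#'
#' One dot per accepted spectrum, grouped by peptide and faceted by
#' protein: the per-protein overview used to eyeball consistency of
#' q-values across peptides and spectra.
#'
#' @param measurements Measurement tibble from [quantify_pairs()]; only
#'   accepted rows are shown.
#' @param accessions Optional accession filter.
#' @return A ggplot object.
#' @export
plot_q_values <- function(measurements, accessions = NULL) {
  d <- dplyr::filter(measurements, .data$accepted)
  if (!is.null(accessions)) {
    keep <- vapply(strsplit(d$accessions, ";"),
                   function(a) any(a %in% accessions), logical(1))
    d <- d[keep, ]
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$peptide, y = .data$q)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::facet_wrap(~accessions, scales = "free_x") +
    ggplot2::geom_hline(yintercept = c(0.2, 0.8), linetype = "dotted") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "q-value (heavy fraction)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
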