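# Independent brute-force isotopologue oracle: enumerates every way of
# assigning isotopes to the atoms of a composition, accumulating exact
# probability and mass per nominal-mass bin. Deliberately shares no code
# with the package's convolution path; only the isotope reference table is
# common (it is data, not algorithm).

# All count vectors (c1..ck) with sum n, as rows.
oracle_count_vectors <- function(k, n) {
  if (k == 1) return(matrix(n, ncol = 1))
  out <- NULL
  for (c1 in 0:n) {
    rest <- oracle_count_vectors(k - 1, n - c1)
    out <- rbind(out, cbind(c1, rest))
  }
  out
}

# Per-element table of (total probability, total mass) over isotope-count
# assignments of n atoms.
oracle_element_states <- function(masses, abundances, n) {
  counts <- oracle_count_vectors(length(masses), n)
  prob <- apply(counts, 1, function(cc) {
    exp(lgamma(n + 1) - sum(lgamma(cc + 1))) * prod(abundances^cc)
  })
  mass <- as.numeric(counts %*% masses)
  data.frame(prob = prob, mass = mass)
}

# Full envelope by cross-element enumeration, binned on the unit-mass grid.
# Returns a data.frame(nominal, prob, centroid) with nominal relative to the
# all-lightest-isotope state.
oracle_envelope <- function(composition, n15 = NULL) {
  iso <- isotope_table()
  states <- list(data.frame(prob = 1, mass = 0))
  for (el in names(composition)) {
    n <- composition[[el]]
    if (n == 0) next
    d <- iso[iso$element == el, ]
    d <- d[order(d$mass), ]
    ab <- d$abundance
    if (el == "N" && !is.null(n15)) ab <- c(1 - n15, n15)
    elem <- oracle_element_states(d$mass, ab, n)
    new <- list()
    for (s in seq_len(nrow(states[[1]]))) {
      new[[s]] <- data.frame(
        prob = states[[1]]$prob[s] * elem$prob,
        mass = states[[1]]$mass[s] + elem$mass)
    }
    states <- list(do.call(rbind, new))
  }
  full <- states[[1]]
  mono <- min(full$mass)
  nominal <- round(full$mass - mono)
  agg_p <- tapply(full$prob, nominal, sum)
  agg_pm <- tapply(full$prob * full$mass, nominal, sum)
  out <- data.frame(nominal = as.integer(names(agg_p)),
                    prob = as.numeric(agg_p),
                    centroid = as.numeric(agg_pm / agg_p))
  out[out$prob > 0, ]
}
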