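# Reference tables: residue elemental formulas and stable-isotope
# masses/abundances. Both ship as plain TSV under inst/extdata so the values
# are versioned with the package and auditable.

elements_tracked <- c("C", "H", "N", "O", "S")

#' Stable-isotope reference table
#'
#' Masses (Da) and natural abundances of the stable isotopes of C, H, N, O
#' and S, the elements occurring in unmodified peptides. Abundances sum to 1
#' within each element; masses are strictly increasing within an element.
#'
#' @return A tibble with columns `element`, `isotope` (nominal mass number),
#'   `mass` (Da) and `abundance` (fraction).
#' @export
#' @examples
#' isotope_table()
isotope_table <- function() {
  path <- system.file("extdata", "isotopes.tsv", package = "n15quant",
                      mustWork = TRUE)
  tab <- readr::read_tsv(path, col_types = "cidd", progress = FALSE)
  stopifnot(all(abs(tapply(tab$abundance, tab$element, sum) - 1) < 1e-9))
  tab
}

#' Amino-acid residue composition table
#'
#' Elemental formulas of the 20 standard amino-acid residues (as incorporated
#' in a peptide chain, i.e. minus one water relative to the free amino acid).
#'
#' @return A tibble with columns `residue`, `name`, `formula`, and one
#'   integer column per element (`C`, `H`, `N`, `O`, `S`).
#' @export
#' @examples
#' residue_table()
residue_table <- function() {
  path <- system.file("extdata", "amino_acids.tsv", package = "n15quant",
                      mustWork = TRUE)
  tab <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  counts <- t(vapply(tab$formula, parse_formula, integer(5)))
  dplyr::bind_cols(tab, as_tibble(counts))
}

# "C6H12N4O" -> named integer vector over elements_tracked.
parse_formula <- function(formula) {
  m <- gregexpr("([CHNOS])([0-9]*)", formula, perl = TRUE)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    abort(paste0("Cannot parse formula '", formula, "'"))
  }
  counts <- setNames(integer(length(elements_tracked)), elements_tracked)
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- substr(p, 2, nchar(p))
    counts[el] <- counts[el] + if (nzchar(n)) as.integer(n) else 1L
  }
  counts
}

# Cached copies: both tables are immutable reference data.
the <- new.env(parent = emptyenv())

get_isotopes <- function() {
  if (is.null(the$iso)) the$iso <- isotope_table()
  the$iso
}

get_residues <- function() {
  if (is.null(the$res)) {
    tab <- residue_table()
    mat <- as.matrix(tab[, elements_tracked])
    rownames(mat) <- tab$residue
    the$res <- mat
  }
  the$res
}

# Per-element isotope (mass, abundance) list, lightest first.
isotope_list <- function() {
  if (is.null(the$isolist)) {
    tab <- get_isotopes()
    the$isolist <- lapply(split(tab, tab$element), function(d) {
      d <- d[order(d$mass), ]
      list(mass = d$mass, abundance = d$abundance)
    })
  }
  the$isolist
}
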