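---
title: "Quantifying 14N/15N-labeled proteomes from MALDI peak lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 14N/15N-labeled proteomes from MALDI peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n15quant)
```

## The measurement model

Two samples — one grown on ¹⁴N medium, one on ¹⁵N medium — are mixed 1:1
by protein amount, separated by SDS-PAGE into gel segments, digested with
trypsin, fractionated by nano-LC onto MALDI targets, and measured in MS
mode. Every peptide then contributes two isotope envelopes to the mixed
spectrum: the light envelope at its natural-abundance position and the
heavy envelope shifted up by roughly 0.997 Da per nitrogen atom. The
quantity of interest is the heavy fraction

$$q = \frac{\sum I_{^{15}N}}{\sum I_{^{14}N} + \sum I_{^{15}N}},$$

summed over the matched envelope slots of each side. `q` is symmetric
under label exchange (`q -> 1 - q`), turns into a fold change as
`q/(1-q)`, and degenerates gracefully: a peptide present in one tissue
only gives exactly 0 or 1.

The central assumption is that mixing happens *before* digestion and
fractionation, so both envelope partners experience identical losses; the
intensity ratio within one spectrum is then an unbiased abundance ratio
without any cross-run normalization. The package deliberately provides no
normalization machinery for the same reason.

### Theoretical envelopes at partial enrichment

Metabolic labeling is never complete, so the heavy envelope must be
predicted at the actual enrichment $p$ (fraction of nitrogen atoms that
are ¹⁵N). For each element the isotope distribution of $n$ atoms is a
multinomial; for nitrogen the natural abundances are replaced by
$(1-p, p)$. Per-element distributions are convolved across elements on
the unit-mass grid: MALDI-TOF reflector data resolves one centroid per
nominal mass for peptides, so fine isotopologue structure is aggregated,
with each bin's centroid at the abundance-weighted mean mass. Charge is
fixed at 1 (protonated), as MALDI produces almost exclusively singly
charged peptide ions.

Envelopes are truncated to the most intense contiguous window of
`max_peaks = 8` slots and renormalized; for peptides under ~3 kDa this
window carries more than 99.9% of the intensity. The isotope masses and
abundances ship as a versioned plain-text table (`inst/extdata/`), as do
the residue formulas; the correctness of the convolution is pinned in the
test suite against an independent brute-force enumerator of all
isotopologue assignments (agreement to 1e-9).

Ambiguity codes (B, J, O, U, X, Z) are rejected outright rather than
approximated: a wrong composition silently shifts the envelope and the
shape filter would then discard good spectra for opaque reasons.

## Matching and the two filter families

For each library peptide the light and heavy envelopes are sought in every
quantification spectrum. Matching takes, per theoretical slot, the nearest
centroid within 30 ppm (ties go to the more intense peak), and requires at
least `min_matched = 3` consecutive filled slots including the
theoretically most intense one — the shape test below needs at least two
adjacent pairs. 30 ppm mirrors the usual database-search tolerance of
internally calibrated MALDI-TOF data; it is a setting, not a constant.

Mass alone is a weak identifier: many sequences share a nominal mass, and
in an isoform family near-isobaric substitutions (Q/K at 36 mDa, I/L at
exactly 0) are common. Two filter families remove such false pairs:

* **Envelope shape.** For every adjacent pair of matched slots the bounded
  ratio $r_i = I_{i+1}/(I_i + I_{i+1})$ is compared between experiment and
  theory; the envelope passes only if every $|r^{exp}_i - r^{theo}_i|$ is
  at most the threshold (default 0.05). The bounded form was chosen over
  the raw quotient $I_{i+1}/I_i$ because it stays in $[0,1]$, treats both
  orientations symmetrically, and does not explode when the denominator
  slot is weak. The 0.05 default separates compositions differing by a
  few carbons at 2% intensity noise while tolerating that noise itself
  (a 2% CV perturbs $r$ by well under 0.01).
* **Position.** A legitimate pair must appear (1) in the gel segment of
  its MS/MS identification (±1 segment), in a segment whose
  molecular-weight window contains the intact protein for some oligomeric
  state in `{1, 2}` — membrane proteins such as aquaporins band both as
  monomers and dimers — and (2) at the same LC elution position, compared
  as mid-fraction retention times across the 48-fraction identification
  schedule and the 192-fraction quantification schedule, within
  `elution_tol_min = 1.5` min. The tolerance generously covers the
  half-interval quantization of the two schedules (0.35 + 0.075 min)
  while rejecting peptides one gradient region away.

Spectra where the light tail and the heavy window claim the same nominal
slot (possible for low-nitrogen peptides) are flagged as overlapping and
excluded rather than apportioned — intensity splitting between unresolved
partners is not identifiable from centroided data. Similarly, a
single-side call (q of exactly 0 or 1) is accepted only when the partner
envelope is entirely absent; partial partner signal that merely failed the
consecutive-slot rule marks the spectrum ambiguous.

All thresholds live in one settings list (`default_settings()`,
YAML-serializable). None of them were published with the original
workflow; each default here is documented above and exposed rather than
baked in.

## Aggregation

Accepted measurements aggregate as the arithmetic mean of per-spectrum q
per peptide (SD over spectra; 0 for a single spectrum), and per protein as
the mean over *unique*-peptide means (SD over peptide means; with a single
unique peptide the peptide's own spectrum SD is reported). Shared peptides
never enter protein summaries: they cannot attribute abundance to one
family member. The per-spectrum q, not the intensity-weighted pooled q, is
the aggregation unit, matching the convention of reporting an SD over
spectra.

## Labeling efficiency

Enrichment is estimated by scanning $p$ from 0.90 to 1.00 in 0.001 steps
(matching the one-decimal-percent reporting convention) and minimizing the
mean squared adjacent-ratio difference between observed heavy envelopes
and theory at each candidate $p$. The comparison aligns slots by
extra-neutron index against the untruncated candidate distribution;
observed slots a candidate cannot populate count as zero intensity, which
penalizes boundary candidates honestly, and a candidate with no comparable
pairs at all scores no fit. Estimates landing on a grid edge are flagged
(`boundary`) — unlabeled input, for instance, pins to the low edge with a
poor fit rather than producing a plausible-looking number. Efficiency
should be estimated on spectra of purely labeled material; in mixed
spectra the light envelope of low-nitrogen peptides reaches into the heavy
window and biases the fit low.

## Shared peptides and isoform ratios

A peptide shared by isoforms reports the abundance-weighted mean of their
heavy fractions, $q_{shared} = \sum_i w_i q_i$. For two isoforms whose
unique peptides supply $q_1 \neq q_2$ this inverts to
$w_1 = (q_{shared} - q_2)/(q_1 - q_2)$ and the abundance ratio $w_2/w_1$
(reported raw and rounded to one significant figure, the precision such
statements support). The inversion assumes the shared peptide ionizes and
is detected with equal efficiency from all parents — reasonable for an
identical sequence, but stated as an explicit flag on every output. Two
honesty guards: a shared q outside $[\min(q_1,q_2), \max(q_1,q_2)]$ is
reported infeasible (with the clamped boundary solution), and
$|q_1 - q_2| < 0.1$ raises a conditioning warning since the weight error
scales as $1/|q_1 - q_2|$. For three or more isoforms no point estimate
exists; `family_bounds()` reports feasibility, the feasible weight
interval when exactly one component is unquantified, and the family-level
aggregate $q_{shared}$ with its tissue ratio. Least-squares deconvolution
across multiple shared peptides is deliberately out of scope.

## The simulator: what it emulates, what it does not

`simulate_experiment()` generates the full artifact chain with known
truth: a deterministic synthetic proteome (by default a 13-member
aquaporin-like isoform family at ≥ 90% identity — mutations avoid K, R and
P so the cleavage pattern, and hence peptide alignment across isoforms, is
preserved — plus unrelated background proteins), tryptic digestion, gel
segments assigned from intact molecular weight on a 36-segment
log-spaced gel model, LC fractions from a Kyte-Doolittle hydropathy proxy
mapped monotonically into the collection window of both schedules
(identification on 48 × 0.7 min, quantification on 192 × 0.15 min, both
starting at 28 min), and per-spectrum light/heavy envelopes scaled to
$(1-f)$ and $f$ of the peptide's intensity.

The noise model is: log-normal multiplicative intensity error (default
CV 2%, the reproducibility scale of well-behaved MALDI ratio data),
uniform m/z jitter (±5 ppm, comfortably inside the 30 ppm matching
tolerance after internal calibration), per-peak dropout (1%), an optional
additive intensity floor, and optional random background peaks.
`inject_confounders()` adds labeled decoys for filter validation:
correct-shape envelopes at wrong gel segments or wrong LC fractions
(which the positional filters must remove completely) and
atom-doubled-composition envelopes at correct positions and masses (which
the shape filter must remove).

What the simulator does *not* emulate: chromatographic peak shapes and
fraction-boundary splitting, detector saturation, matrix adducts and
in-source decay, correlated noise across slots, and real retention-time
irreproducibility between runs (the hydropathy proxy is perfectly
consistent between the simulated identification and quantification runs).
Passing tests therefore demonstrate the correctness of the computation and
the discriminating power of the filters under controlled noise — not
robustness to every pathology of real spectra.

## Numerical choices and degenerate inputs

* Envelope bins are exact integers of extra neutron count; the convolution
  allocates `N + max_peaks + 24` bins so the fully labeled region is always
  reachable, and truncation picks the best contiguous window afterwards.
* Matching tie-breaks (two centroids equidistant from a slot) go to the
  higher intensity, mirroring how a human would read a spectrum.
* `q` with both sums zero is an error, not NaN; empty spectra and empty
  acceptance sets propagate as empty tibbles, not failures.
* Equal component q-values make the two-isoform inversion singular and are
  rejected as unidentifiable.
* Problem sizes in the test suite are desk-scale by design: proteomes of
  2-16 proteins, tens to hundreds of spectra, 20-envelope efficiency
  fits, and a nine-point mixing series with ≥ 20 accepted spectra per
  level. These sizes make every distributional claim testable in minutes
  while leaving the per-operation arithmetic identical to full-scale runs.

## Known limitations

Charge states above 1, variable modifications, phosphopeptides, profile
(non-centroided) input, FDR machinery, cross-run normalization and
protein inference beyond the unique-peptide roll-up are out of scope. The
gel molecular-weight model is an idealized log-spaced ladder; real gels
need a calibrated segment table, which the settings accept. I/L
equivalence is off for bookkeeping but should be enabled for
uniqueness-critical decisions, since mass-only matching cannot separate
isobaric residues.
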