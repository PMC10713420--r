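---
title: "Methods and design notes for pepdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for pepdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdiff)
```

`pepdiff` implements the computational arm of a two-group comparative
tissue peptidomics study. This vignette records the models, conventions and
numerical choices behind each stage, the places where the design was
genuinely open and how we resolved them, and what validation on synthetic
data does and does not establish.

## Data model and conventions

The unit of analysis is one identified peptide: sequence (strict 20-letter
alphabet; B, J, O, U, X, Z are rejected at the boundary), precursor
accession, modification list (`name@pos`, `pos` a 1-based residue index or
`N-term`), and one intensity per sample. Two conventions are applied
everywhere and never mixed:

* **Coordinates are 1-based inclusive**, matching the interval style of
  curated domain annotations ("3-376"). No half-open intervals cross the
  I/O boundary.
* **Missing is not zero.** An empty intensity cell means absent
  quantitation and is excluded from means, CVs and tests; a zero is an
  informative reporter value and participates (after a half-minimum offset
  when logging). This distinction is preserved on round-trip.

## Differential expression

Testing uses Student's pooled-variance two-tailed t-test on log2
intensities. The pooled (not Welch) form is the primary test because the
source convention for this design is the ordinary two-sample t-test;
Welch's correction is available behind `welch = TRUE`. Log2 transformation
is the standard choice for reporter-ion intensities, whose technical noise
is approximately log-normal; it also makes the fold-change estimate the
ratio of geometric means, which is unbiased on the log scale.

A peptide is called differentially expressed when `p < 0.01` and
`max(FC, 1/FC) >= 2`. The fold gate is applied inclusively (`>= 2`).
Direction follows group order in the design file (group 2 over group 1);
relabeling groups or permuting samples within that order leaves every
statistic unchanged. No multiple-testing correction enters the headline
call — the dual gate is itself conservative and matches field practice —
but Benjamini–Hochberg q-values are always appended so users can filter on
FDR instead.

Degenerate inputs are defined, not crashed on: zero variance in both groups
with equal means reports `p = 1` and a `zero_variance` flag; peptides with
fewer than two non-missing values in either group are returned with
`testable = FALSE` rather than dropped.

Median-ratio normalization equalizes per-sample medians computed over
complete-case peptides, rescaling to the median of medians so an already
balanced matrix is a fixed point. The source data for this class of
experiment arrive ratio-scaled from the quantitation software, so
normalization defaults to a gentle method and `"none"` is supported.

PCA is complete-case (peptides quantified in every sample), centered per
peptide, computed by SVD. Loading-column signs are fixed by making each
column's largest-magnitude entry positive, which makes results reproducible
across BLAS implementations. Heatmap tables z-score each peptide row and
order rows by average-linkage hierarchical clustering of Euclidean
distances.

## Physicochemical panel

The descriptor panel reproduces the ProtParam conventions from the
published constant tables, vendored in `R/constants.R` with citations:
Kyte–Doolittle hydropathies (GRAVY is their arithmetic mean), Ikai's
aliphatic-index coefficients (2.9 for Val, 3.9 for Ile/Leu, on mole
percents), the Guruprasad 400-entry dipeptide instability weight table
(`II = (10/L) Σ DIWV`, stable below 40), the N-end-rule half-life lookup
(mammalian reticulocyte in vitro by default; yeast and E. coli tables
included; entries published as bounds, e.g. ">20 h" for N-terminal Pro, are
stored as the bound with an `is_bound` flag), and the Bjellqvist pKa set
with residue-dependent α-amino pKa.

The isoelectric point is the root of the net-charge function

$$ q(\mathrm{pH}) = \sum_{\text{pos}} \frac{1}{1+10^{\mathrm{pH}-pK_a}}
 - \sum_{\text{neg}} \frac{1}{1+10^{pK_a-\mathrm{pH}}} $$

found by bisection on [0, 14] to |q| < 1e-4. Because q is strictly
decreasing in pH the root is unique; tests verify the bisection against a
0.001-step grid scan of the same function.

Labeled monoisotopic masses use the amine-reactive iTRAQ-8plex convention:
+304.2054 Da per free N-terminus and per lysine. This convention
reproduces printed integer masses for both a lysine-free and a
lysine-containing reference peptide, which is how it was fixed; it is a
documented interpretation of the labeling chemistry, not a per-peptide
modification call. Reference tables of this kind can carry residual
modifications (e.g. one Met oxidation adds ≈16 Da) that are not annotated
per row; we do not guess them.

Helical wheels place residue $i$ at $((i-1)\cdot 100^\circ) \bmod
360^\circ$, the idealized α-helix of 3.6 residues per turn. Residue
polarity classes are basic {K, R, H}, acidic {D, E}, polar-uncharged
{S, T, N, Q, C} and nonpolar {G, A, V, L, I, P, M, F, W, Y}. Classing the
aromatics (including Tyr) as nonpolar is required for consistency with the
reference class counts for the GVMVGMGQKDSYVG candidate (ten nonpolar
residues) and matches hydrophobicity-oriented wheel tools.

## Precursor mapping and cleavage profiling

Peptides are located by exact substring search; when that fails the search
is retried with Ile and Leu collapsed, because MS cannot distinguish them —
the match mode is always reported, never silent. Multi-hit peptides take
first-occurrence coordinates with all occurrences recorded. Cleavage
context uses protease nomenclature: at the peptide's N-terminal cut, P1 is
the precursor residue before the peptide and P1′ its first residue; at the
C-terminal cut, P1 is its last residue and P1′ the residue after. Peptides
flush with a protein terminus get sentinels there, and sentinels are
excluded from frequency counts.

"Located in a functional domain" means full containment
(`domain.start <= start` and `end <= domain.end`); every row of the
packaged domain reference satisfies containment, so mere overlap is
reported separately rather than conflated. The cleavage profile counts
residues at four positions (N-terminal P1 and P1′, C-terminal P1 and P1′),
stratified by differential direction; the "dominant" residue is the count
argmax with alphabetical tie-break. The four-position convention is our
interpretation of cleavage-specificity summaries that do not define their
positions; it is symmetric and captures both sides of both cuts.

Because no real precursor database ships with the package, location tests
run against a synthetic scaffold (`pep_actg2_scaffold()`): a 380-residue
sequence that embeds the seven reference candidate peptides at their
published coordinates, each occurring exactly once even under I/L
equivalence. It preserves the coordinate structure being tested and is
clearly labelled synthetic — it is not the real Actg2 sequence, so
descriptor values computed on scaffold regions outside the embedded
peptides are meaningless by design.

## Enrichment

Over-representation uses the hypergeometric upper tail
`p = P[X >= k]` with `X ~ Hypergeometric(N, K, n)`, computed by
`stats::phyper(k - 1, ...)`. The universe defaults to all precursor
accessions in the loaded quant table — the standard background — and is
configurable; whether to query all precursors or DEP precursors only is
left to the caller, as both are defensible. Set-size bounds (default 3 to
500) exclude sets too small or too broad to be informative. BH correction
is applied over the tested sets. Tests verify the tail against exhaustive
enumeration of all C(N, n) draws for small N.

## Candidate ranking

The selection rationale behind candidate tables — stronger differential
expression, longer half-life, more hydrophobic, predicted stable — is
narrative in origin, so the implemented score is an explicit
operationalization, shown after the raw criterion table, never instead of
it. Each criterion becomes a within-table rank (smaller p, larger |log2FC|,
longer half-life, larger GRAVY, stable first; average ranks on ties) and
ranks are combined as a weighted sum with equal default weights;
alphabetical sequence order breaks final ties. Using ranks makes the score
invariant to monotone rescaling of any criterion. On the packaged 7-peptide
panel the equal-weight score is led by the candidates that dominate on
|log2FC| and half-life; the package makes no claim that any particular
candidate must rank first.

## Synthetic peptidome generator

The generator's defaults describe the emulated study: two groups of six
samples; ~1000 precursors of 150–450 residues with i.i.d. composition
(uniform by default; a vertebrate-average option exists — the choice
affects realism, not correctness); memoryless residue-biased proteolysis in
which each peptide bond is cut with probability
`cut_rate × odds[P1]/mean(odds)` (default rate 0.04, giving mean fragment
length ≈ 25 and, after restricting to the 9–99-residue window, on the
order of 10^4 peptides); per-peptide baseline log2 abundance Normal(20, 2);
technical noise log-normal with CV 0.2; 10% of peptides spiked at ±2 log2
units (two doublings, comfortably past the 2-fold gate) with Bernoulli(½)
sign; 5% missing completely at random. One global seed derives a separate
stream per stage, so any stage can be reproduced in isolation and the whole
chain is byte-identical across runs.

Validation against this generator establishes calibration (empirical
type-I error ≈ 0.01 at p < 0.01 under the null), power (sensitivity ≥ 0.8
for 4-fold spikes at the study design), estimation bias (null log2FC
centered at 0; spike estimates within 0.15 of truth on average) and
closed-loop cleavage recovery (configured preferred residues recovered as
profile argmax at 5:1 odds with ≥ 300 peptides). What it does **not**
establish: robustness to the structured missingness, batch effects,
interference/ratio compression and correlated peptides of real
reporter-ion data — the generator's noise is i.i.d. log-normal and its
missingness MCAR by construction. Conclusions about real data should rest
on the method conventions, not on the simulation passing.

## Problem sizes and determinism

The shipped tests exercise the statistical stages at 2 000–5 000 peptides
and the generator at 40–300 precursors — sizes at which binomial tolerances
on calibration checks are tight (3 standard errors) yet the whole suite
runs in well under a minute per file. All stochastic tests fix seeds; all
outputs are deterministic given seed and input, including PCA sign
conventions and tie-breaks (alphabetical throughout).

## Known limitations

- Mapping is exact-substring (plus I/L equivalence); no mismatches or
  indels, no signal-peptide awareness.
- The instability index and N-end-rule half-life are sequence-only
  predictors calibrated on proteins; applied to short endogenous peptides
  they are screening heuristics, not measurements.
- The enrichment module is annotation-source-agnostic and does not model
  GO term ancestry.
- Reference tables printed in source studies can carry inconsistencies
  (a mass-column header off by a factor of 1000; one peptide printed with
  and without a terminal residue in different tables). Packaged fixtures
  store such values verbatim and flag the discrepancy instead of
  reconciling it.
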