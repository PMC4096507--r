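---
title: "Individual diet networks: models, null models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual diet networks: models, null models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietnet)
```

## The problem

A population of predators that looks generalist in aggregate may be a
collection of individual specialists. When each forager's prey list is
recorded — here, provisioning wasps whose females deliver identifiable prey
to their nests across a season — the data form an individual-by-prey-taxon
count matrix, and the structure of inter-individual diet variation becomes a
network question. dietnet implements the four network statistics commonly
used on such matrices, each with its Monte-Carlo null model, the covariate
tests used to probe *why* a topology arises, and a synthetic-matrix
generator whose structure (and its strength) is known, so that every test's
power and calibration can be measured.

## Data model and filtering

The central object is the `diet_matrix`: non-negative integer counts, rows =
individuals, columns = prey taxa. Orientation is a contract, never guessed.
All-zero rows and columns are dropped with a warning, so a season matrix
containing taxa unobserved that year loads cleanly. Before any analysis,
individuals with fewer than 4 prey are removed (`filter_min_prey`); diet
*proportions* from two or three items are too noisy to compare, and the
study design this package mirrors used the same cut-off. Presence/absence
analyses use `to_binary` (cell = 1 iff count ≥ 1).

## The four indices

**E — inter-individual variation.** Pairwise diet overlap is proportional
similarity, `w_jk = 1 − 0.5 Σ_i |p_ij − p_ik|`, on row-proportion vectors;
`E = 1 − mean(w_jk)` over all pairs: 0 when all diets agree, 1 when all
pairs are disjoint. The null model (`bootstrap_diets`) redraws every
individual's diet as a multinomial sample of its own size from the pooled
population proportions; the population is called specialized when observed E
lands above the null's 95% band. Pianka-style overlaps could be added
without changing E's contract; proportional similarity is the field's usual
choice for count data.

**C_ws — relative clustering.** The clustering statistic is an Onnela-type
weighted clustering coefficient (geometric-mean triangle intensity,
normalized per node by `k(k−1)` over the nonzero-weight skeleton) evaluated
on the overlap network *restricted to its significant edges*. An edge is
significant when the observed overlap of that pair exceeds the 95% quantile
of its own null distribution (both rows redrawn from pooled proportions);
per-pair thresholds matter because pairs differ in sample size. The same
thresholds are then applied to bootstrap populations to obtain the null Cw
distribution, so observed and null values are exchangeable under the
no-structure hypothesis. `C_ws = (Cw − mean Cw_null)/D`, with `D` chosen
(1 − mean, or mean) to map any outcome into \[−1, +1\]. The test is
two-tailed at 2.5%/97.5%.

A design note: an early candidate was the triangle-intensity statistic on
the *complete* weighted graph. Measured on generated clustered populations
it moves the wrong way — cross-cluster overlaps collapse, the mean edge
weight dominates the statistic, and clustered populations score *below*
their null. Restricting to the pairwise-significance skeleton (the same
binary association matrices from which cluster membership is read) gives a
statistic that rises under genuine modules; the toy values (all overlaps 1 →
Cw = 1; three nodes with weights 1, 1, 0.125 → Cw = 0.5) are unchanged.

**Cluster extraction.** Dietary clusters are the connected components of the
significant-overlap graph, labelled deterministically (size, then smallest
member id). Components are the plainest reading of "affiliation from the
binary association matrix"; if a data set ever yields one giant component, a
modularity method can be layered on top, but none of the generated or
analysed cases needed it. Singletons are legitimate clusters.

**NODF — nestedness.** For each pair of rows (and of columns) with strictly
unequal marginal totals, the paired score is 100 × shared presences /
smaller total; equal totals score 0 (strict "decreasing fill"). NODF is the
mean over all row and column pairs, 0–100, invariant to input order. The
null is the CE cell-probability model: cell (i, j) is occupied independently
with probability the mean of row fill and column fill; draws with an empty
row or column are redrawn (the redraw count is recorded). One-tailed 95%
rule.

**C-score — checkerboardedness.** Over prey-taxon pairs (columns):
`CU = (r_i − S)(r_j − S)`, normalized per pair by `r_i r_j` and averaged, so
the score is 0 when every pair co-occurs maximally and 1 for a perfect
checkerboard. The column-pair reading follows the never-co-occurring-pair
census that accompanies it (`never_cooccurring_pairs`); the raw
Stone–Roberts mean CU is available via `normalize = FALSE`. The null
preserves both margins exactly: a Markov chain of random 2×2 trial swaps.

The swap sampler deserves its own note. Proposing uniformly among 2×2
submatrices and swapping only checkerboards is a symmetric chain whose
stationary law is uniform over the fixed-margin set — *provided samples are
taken at fixed attempt intervals*. Sampling whenever a swap succeeds weights
each matrix by its number of swappable submatrices — a bias the 3×3
enumeration oracle in the test suite is designed to catch, and one that
matters in practice: it drags the null toward checkerboardness and weakens
the test. dietnet samples every `5 × fill` attempts
after a `50 × fill` burn-in. Matrices with no swappable submatrix yield a
flagged degenerate null.

## Monte-Carlo conventions

All p-values use the add-one estimator, `p = (1 + #{null ≥ obs})/(n + 1)`,
ties counting against the observed value; two-sided p is twice the smaller
tail, capped at 1. Verdicts use `p ≤ α` (α = 0.05 one-tailed, 0.025 per tail
two-tailed), which coincides with the quantile rules at large n and has
exactly nominal level under exchangeability at any n. Default resampling
depth is 10000, configurable downward. Every ensemble records its scheme,
size and seed; a master seed spawns per-pair and per-replicate sub-streams
by counter (`derive_seed`, a fixed integer hash feeding R's Mersenne
Twister), so per-pair nulls share no draws and results are reproducible
bit-for-bit.

## Covariate tests

The factor battery wraps the classical procedures behind a uniform result
type, applying the transforms where the analysis calls for them and
recording them: Pearson correlation of per-taxon predator counts against
ln-availability (inner join on taxa, positive availability required);
least-squares regression of the percentage of the population's taxa
captured on body mass; one-way ANOVA with Tukey HSD across clusters;
mean-centered Levene's test of mass variance across years with per-group CV;
a paired t on first-vs-last-nest breadth; a Student's t comparing |Δ mean
prey mass| between never- and ever-co-occurring taxon pairs; per-female mean
capture-day scores; and a Student's t on square-root-transformed inter-nest
distances, within- vs between-cluster pairs. Pair-level tests treat pairs as
independent — consistent with their customary degrees of freedom, and a
known pseudo-replication caveat. These are deliberately thin wrappers over
`stats` and `car`; the package's contribution is the network machinery, not
the classical tests.

## The synthetic generator

`population_spec` fixes the study regime: 12 individuals (14 in the
clustered scenarios), 16 taxa, per-individual totals uniform on 4–30, a
dominant taxon holding half of all items and the remainder decaying
geometrically (ratio 0.85 — flat enough that essentially every taxon is
realized at this scale, as in deposited matrices, which by construction list
only observed taxa). Structure modes and the meaning of `strength`:

* **null** — rows i.i.d. multinomial from the pooled proportions; the exact
  null hypothesis of the diet bootstrap, used for type-I calibration.
* **nested** — a simulated body mass (normal, 96 ± 15 mg) orders niche
  breadth; individual of mass rank r accesses the top `b_r` taxa, breadths
  spanning 1 to 16. Within the accessible set, weights interpolate from the
  pooled proportions toward a mild geometric rank profile (ratio 0.8) so
  that broad individuals realize their breadth instead of resampling the
  dominant taxon; out-of-niche weight shrinks as `(1 − s)⁴`.
* **competitive_refuge / distinct_preferences** — cluster diets are convex
  mixtures `(1 − s′)·pooled + s′·component` with a concave response
  `s′ = 1 − (1 − s)²`. Competitive-refuge components share the dominant
  taxon at reduced weight (0.3) plus a private geometric block of secondary
  taxa; distinct-preferences components concentrate on the cluster's own
  top-ranked taxon, so at strength 1 clusters specialize completely and the
  partition is exactly recoverable from the significance graph.
* **checkerboard** — taxa are paired along the abundance rank and
  individuals alternate between two forager sets, each allowed one member of
  every pair; the excluded member keeps `(1 − s)⁴` of its weight. The steep
  leakage curve is deliberate: a single stray capture re-establishes binary
  co-occurrence, so presence/absence exclusion demands near-zero leakage.

Strength 0 reduces every mode to the null generator (checked
distributionally in the tests); power curves are monotone in strength. These
calibrations were chosen so that the generator's advertised regimes are
detectable by the package's own tests at the study's sample sizes —
clustered verdicts and exact recovery in ≥ 90% of strongly segregated
populations, nestedness in ≥ 95%, checkerboard verdicts in ≥ 90% — and then
frozen.

What the generator does *not* emulate: seasonal turnover within a matrix,
observation error in prey identification, unequal cluster sizes (available
through the spec but not defaulted), spatial foraging structure, or
correlation between body mass and total prey count. Passing tests therefore
demonstrate calibration and power under the stated mechanisms at the study
scale, not that real populations obey those mechanisms.

## Numerical choices and degenerate inputs

Row proportions must sum to 1 within 1e-12. Overlap weights are clipped at 0
against rounding. A diet matrix with a single effective taxon yields a
degenerate E null (all zeros) and p = 1, flagged rather than erroneous.
ANOVA on constant values returns F = 0 with a flag; correlations on constant
vectors are flagged undefined; zero-variance paired differences return
p = 1 flagged. CE redraws are capped at 100 with a warning. The C_ws
normalization returns 0 when its denominator vanishes (null mean 0 or 1).
Cluster labels break ties lexically so relabelled inputs give permuted but
identical partitions.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely from generated data:
single-season analyses at n = 12–14 individuals with 150–10000 resamples;
calibration loops of 100–1000 replicates at 199–400 resamples each. These
sizes give binomial standard errors comfortably inside the asserted bands
(e.g. ±0.7 percentage points for the type-I check at 1000 replicates) while
keeping the whole suite a few minutes long.

## Known limitations

The exact formulas used by the original Dieta1/ANINHADO toolchain for the
weighted clustering coefficient, its normalization, and the CE variant are
not published in detail; dietnet's choices are documented above and fixed,
but numerical equality with those programs' output on the same data is not
guaranteed — the deposited study matrices would be required to calibrate
the dialect, and they are not distributable with this package. The diet
bootstrap uses plug-in pooled proportions (the only option available to a
test), which makes the E test mildly conservative-to-nominal rather than
exact at small sample sizes; the shipped calibration check asserts its
type-I rate stays within 3–7% at the study scale.
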