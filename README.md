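# dietnet

Network analysis of individual diet specialization for predator populations
sampled as individual × prey-taxon count matrices — the kind of data produced
when every prey item delivered by marked, individually followed foragers
(provisioning wasps, raptors, otters, ...) is identified and tallied per
individual over a season.

A population that is generalist in aggregate may be built of individual
specialists, and those specialists can organize in qualitatively different
ways. dietnet computes the four network statistics used to tell these
architectures apart, each against its own Monte-Carlo null model:

* **E** — inter-individual diet variation: `E = 1 − mean(w_jk)` over all
  pairs, with `w_jk = 1 − ½ Σ_i |p_ij − p_ik|` the proportional similarity of
  diet proportion vectors. Null: every individual redrawn multinomially from
  the pooled population diet, preserving its number of prey (10 000
  bootstraps, one-tailed 95% rule).
* **C_ws** — relative clustering in [−1, 1]: an Onnela-type weighted
  clustering coefficient of the overlap network restricted to its
  *significant* edges (per-pair 95% bootstrap thresholds), normalized by its
  null expectation; two-tailed 2.5%/97.5% rule. Dietary clusters are the
  connected components of the significant-overlap graph.
* **NODF** — nestedness (0–100) of the presence/absence matrix, overlap and
  decreasing fill over all row and column pairs; null: CE cell-probability
  model (occupancy probability = mean of row and column fill).
* **C-score** — checkerboardedness (0–1) over prey-taxon pairs,
  `(r_i − S)(r_j − S)/(r_i r_j)` averaged; null: fixed-margin sequential
  trial-swap ensemble; plus the census of never-co-occurring prey pairs.

Around the indices: the minimum-prey filter (≥ 4 items per individual),
CSV/TSV readers and Pajek `.net`/`.clu` export, the classical covariate tests
used to probe *why* a topology arises (prey-availability correlation,
mass–niche-breadth regression, cluster ANOVA + Tukey, Levene variance
homogeneity, paired first/last-nest shift, co-occurrence mass-difference,
temporal activity scores, inter-nest distances), and a synthetic population
generator with tunable nested / clustered / checkerboard structure whose
power properties are verified in the test suite.

## Worked example

A small synthetic season (14 foragers, competitive-refuge structure at
strength 0.8, bundled as a CSV fixture) through the whole pipeline:

```r
library(dietnet)
path <- system.file("extdata", "synthetic_cr2009like_matrix.csv", package = "dietnet")
m <- filter_min_prey(read_diet_matrix(path, season = "demo"), 4)
m
#> Diet matrix [demo]: 14 individuals x 14 prey taxa, 240 items

e_null_test(m, n_boot = 2000, seed = 1)
#> E = 0.6132  (null mean 0.4114, n = 2000 diet_bootstrap resamples, seed 1)
#>   p = 0.0004998, verdict: specialized

cws_index(m, n_boot = 2000, seed = 1)
#> C_ws = 0.1992  (null mean 0.0375, n = 2000 diet_bootstrap resamples, seed 1)
#>   p = 0.04398, verdict: clustered

nodf_test(to_binary(m), n_null = 2000, seed = 1)
#> NODF = 45.4121  (null mean 37.7856, n = 2000 CE resamples, seed 1)
#>   p = 0.08646, verdict: not significant

swap_null_test(to_binary(m), n_null = 2000, seed = 1)
#> C = 0.5158  (null mean 0.5222, n = 2000 swap resamples, seed 1)
#>   p = 0.7676, verdict: neither

extract_clusters(significant_overlap_graph(m, n_boot = 2000, seed = 1))
#> Cluster assignment: 8 clusters (sizes 5, 3, 1, 1, 1, 1, 1, 1) over 14 individuals
```

Reading: the population is significantly specialized (observed E far above
its bootstrap null) and significantly clustered (C_ws above the null band),
while neither nested nor checkerboarded — individuals share the dominant
prey but split into groups over the alternative prey. Two substantial
dietary groups (5 and 3 females) emerge from the significant-overlap graph;
the remaining females are too weakly sampled to attach significantly, and
stay as singletons. `analyze()` runs all four tests for several seasons at
once and writes a season report CSV, cluster tables, the never-co-occurring
pair list and Pajek exports; `simulate_population()` writes a generated
matrix plus its ground truth. A thin command-line wrapper over both lives in
`inst/cli/dietnet.R`.

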