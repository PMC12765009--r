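# vocalid

Vocal individuality metrics for bioacoustic call tables.

`vocalid` quantifies how much individual identity information a call type
carries and how that information is distributed between callers. It was
built around territorial calls of the little owl (*Athene noctua*) — short
"hoook" calls described by a peak-frequency contour (PFC) resampled to 10
evenly spaced points plus call duration — but works for any call type
reducible to a fixed per-call feature vector. It is aimed at
behavioural ecologists comparing vocal individuality between populations,
density conditions, or social contexts.

## What it computes

Starting from a call table (one row per call: individual, group, duration,
10 PFC values in Hz), the features are centred, scaled and decorrelated by
PCA; all metrics operate in that score space.

- **Beecher's information statistic** `HS = Σ_c 0.5 log2(SS_total,c / SS_within,c)`
  over uncorrelated components *c* — bits of identity information per call;
  `floor(2^HS)` is the number of distinguishable signatures. Reported both
  summed over all components and over components with a significant
  individual effect (one-way ANOVA, p < 0.05).
- **Discrimination score** `DS` — percent of calls assigned to the correct
  individual by linear discriminant analysis with leave-one-out
  cross-validation — and the **index of vocal stereotypy**
  `IVS = DS / (100/n)`, the chance-corrected version.
- **WID / BID** — each individual's mean Euclidean distance of calls to its
  own centroid (within-individual consistency) and the distance from the
  population centroid to the individual's centroid (between-individual
  distinctiveness).
- **Acoustic niche overlap (ANO)** — under a Bayesian multivariate-normal
  model per individual (normal–inverse-Wishart posterior), the Monte-Carlo
  probability that a call from a focal individual falls inside another
  individual's alpha-level niche ellipsoid (alpha = 0.99, 10,000 draws by
  default), summed over all other individuals.
- **Group comparisons** — two-sided Wilcoxon rank-sum tests with median/IQR
  summaries of per-individual WID, BID and ANO between two conditions.
- **Synthetic call populations** — a hierarchical Gaussian generator
  (individual mean contour + within-individual noise) with known ground
  truth, used for parameter-recovery and power checks.

## Worked example

Simulate a two-condition study — 14 "clumped" males given three times the
between-individual contour spread of 10 "isolated" males, 25 calls each —
and run the full comparison:

```r
library(vocalid)

study <- simulate_two_condition_study(
  sim_config(n_individuals = 14, calls_per_individual = 25,
             sigma_b = c(rep(90, 10), 0.06), sigma_w = c(rep(35, 10), 0.025),
             group_label = "CLUMPED", seed = 101),
  sim_config(n_individuals = 10, calls_per_individual = 25,
             sigma_b = c(rep(30, 10), 0.02), sigma_w = c(rep(35, 10), 0.025),
             group_label = "ISOLATED", seed = 102))

report <- run_compare(list(study$dense$table, study$sparse$table),
                      config = list(seed = 7, n_mc = 2000, n_draws = 500))
print(report)
```

```
Sample-wide metrics:
     group n_individuals mean_calls_per_individual hs_all hs_significant
1  CLUMPED            14                        25 12.273         12.273
2 ISOLATED            10                        25  3.868          3.834
  n_signatures ds_percent chance_percent   ivs
1         4948      99.71          7.143 13.96
2           14      81.20         10.000  8.12

Per-individual comparisons (Wilcoxon rank sum):
  metric  group1   group2   w         p        method significant n1 median1
1    wid CLUMPED ISOLATED   0 1.020e-06         exact        TRUE 14 1.32355
2    bid CLUMPED ISOLATED 119 3.067e-03         exact        TRUE 14 2.92668
3    ano CLUMPED ISOLATED   0 4.449e-05 normal_approx        TRUE 14 0.00125
     iqr1 n2 median2   iqr2
1 0.07101 10   2.409 0.1221
2 0.35447 10   2.254 0.5231
3 0.00775 10   0.717 0.1854
```

Reading it: the high-individuality condition carries ~12 bits of identity
information (thousands of distinguishable signatures) against ~3.9 bits
(14 signatures) in the sparse condition; nearly every call is classified
to the right caller (DS 99.7% vs 81.2%, IVS 13.96 vs 8.12); and its median
aggregate niche overlap is essentially zero against 0.72 — clumped-style
callers barely intrude on each other's acoustic niches. All three
per-individual metrics differ significantly (p < 0.05). Note WID is
*smaller* in the dense condition only because features are standardized
within each condition — see the methods vignette.

Field data come in through `read_call_table()` (a flat TSV/CSV dialect, or
Raven-style selection tables with variable-length contour columns, which
are resampled to 10 evenly spaced points by linear interpolation). A thin
command-line wrapper lives at `inst/cli/vocalid.R`
(`simulate` / `metrics` / `ano` / `compare` / `report`).

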