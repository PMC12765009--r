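---
title: "Methods: quantifying vocal individuality with vocalid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying vocal individuality with vocalid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vocalid` measures individual identity information in animal calls from
tables of per-call features. This vignette explains the statistical model
behind each metric, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the methodology left the details open.

## The feature space

Each call is an 11-vector: a peak-frequency contour (PFC) resampled to 10
points evenly spread in time over the call (Hz), plus call duration (s).
Contours of any length are reduced by linear interpolation at time
fractions $i/(k-1)$, $i = 0,\dots,k-1$, endpoints included
(`resample_evenly()`). Two remarks on that choice:

* Time-normalized even sampling is what makes calls of different durations
  comparable; it is deterministic and call-local. A dynamic-time-warping
  alignment would make each call's features depend on which other calls
  are in the sample, so it is deliberately not used, even though
  contour-extraction utilities in the field often sit inside DTW toolkits.
* Including both endpoints preserves onset and offset frequency, which are
  often the most individual parts of a contour. Bin-midpoint sampling
  would be equally defensible; this package declares the endpoint
  convention and keeps it fixed.

Features are centred and scaled to unit sample standard deviation
(denominator $n-1$), then decorrelated by PCA on the sample covariance of
the z-scores (`call_pc_scores()`). All components are retained and scores
are *not* re-scaled to unit variance: the per-component variance ratios
are exactly the information Beecher's statistic decomposes. Eigenvector
signs are fixed deterministically (largest-magnitude loading positive) so
score files reproduce across platforms. When a sample has no more calls
than features the trailing components have near-zero variance; they are
kept but flagged, and the niche-overlap pipeline caps its dimensionality
below them.

## Beecher's information statistic (HS)

For each (uncorrelated) component, a one-way decomposition over
individuals gives the total and within-individual sums of squares, and

$$HS_c = \tfrac12 \log_2 \frac{SS_{\mathrm{total},c}}{SS_{\mathrm{within},c}},$$

summed over components to give the statistic of the whole call. The
default estimator uses the raw sums-of-squares ratio, exactly as the
statistic is usually described; a mean-square variant
(`estimator = "ms_ratio"`, $SS/(N-1)$ over $SS/(N-k)$) is available
because implementations in the literature differ in whether they apply
the degrees-of-freedom correction. Similarly, published values do not
always state whether components without a significant individual effect
were included, so `calc_hs()` always reports both `hs_all` and
`hs_significant` (components with one-way ANOVA p < 0.05), with the
significant-only sum as the headline default. Neither variant is claimed
to be "the" published computation; both are exposed so either can be
matched. The signature capacity is `floor(2^HS)` — the floor, not
rounding, reproduces all four published (HS, signatures) pairs, including
3.98 → 15 where rounding would give 16.

A property of the PCA route worth knowing: when the number of individuals
is modest (say 20), the sample PCA aligns its components with the
sampling noise of the between-individual scatter matrix (which has only
$k-1$ degrees of freedom). The within-individual scatter is then not
diagonal in the component basis, and by Hadamard's inequality the summed
HS acquires a downward, Jensen-type distortion of order 1–2 bits relative
to the same data measured in a basis where the features are truly
uncorrelated. This is a property of the statistic as practised, not a
software artefact; it is why the package's parameter-recovery tests feed
the simulator's independent features directly to `calc_hs()` (they are
uncorrelated by construction, which is the statistic's actual
requirement), while the end-to-end pipeline keeps the conventional PCA
route.

## Discrimination score, chance and IVS

`calc_ds()` classifies every call with a linear discriminant fitted on
all other calls (leave-one-out cross-validation; shared pooled
within-class covariance), via `MASS::lda(CV = TRUE)`. Priors default to
class call-count proportions — the default of the discriminant routine
the field's metric packages wrap — with uniform priors available. The
score feeds `IVS = DS / (100/n)`, reported to two decimals. DS is
computed on the same PC scores as HS by default; whether the original
computations used scores or raw standardized features is not documented,
so the input is configurable. All components are used unless the pooled
covariance is singular, in which case truncation via `n_components` is
the documented fallback.

## WID and BID

Both are Euclidean distances in score space: WID is the mean distance of
an individual's calls to its own centroid; BID is the distance from the
population centroid (the mean over *all* calls, not the mean of
individual centroids — the two differ with unequal call counts) to the
individual's centroid. Since PCA is an orthogonal rotation, WID and BID
are identical whether computed on standardized features or on the full
set of PC scores; the test suite asserts this to $10^{-8}$.

One consequence of per-condition standardization: scales are relative to
each condition's own total variance. A condition whose individuals are
far apart (large between-individual spread) has its axes shrunk by
standardization, which *reduces* its WID values. WID comparisons between
conditions therefore measure within-individual consistency relative to
the condition's total acoustic variation, not in raw Hz.

## Acoustic niche overlap

Each individual's calls are modelled as a multivariate normal in the
first $m$ score dimensions. Under the standard noninformative conjugate
prior, the posterior is normal–inverse-Wishart: covariance draws from an
inverse-Wishart with $n-1$ degrees of freedom and the sample
sum-of-squares matrix as scale, and mean draws, given the covariance,
normal around the sample mean with covariance $\Sigma/n$
(`fit_niche_posterior()`). The method this adapts states its two tuning
constants — the region level (alpha = 0.99) and the Monte-Carlo draw
count (10,000) — but not the prior; the noninformative conjugate default
of the source method is the only defensible choice and is used here.

The directional overlap of focal individual $i$ in $j$'s niche is the
probability that a call generated from $i$'s distribution falls inside
$j$'s alpha-level ellipsoid (squared Mahalanobis distance below the
chi-square alpha quantile), with both parameter sets integrated over
their posteriors by paired Monte-Carlo draws (`pairwise_overlap()`).
Directionality matters: the focal generates calls, the other defines the
region, and the aggregate ANO of an individual is the *sum* of its row of
the overlap matrix (range 0 to $n-1$) — a sum rather than a mean because
the group designs compared here hold the within-comparison group sizes
fixed.

The niche dimensionality is not documented in the methodology this
package follows. An 11-dimensional normal cannot be stably estimated
from ~25 calls, so the default uses every component with explained
variance above $10^{-8}$, capped so that each individual has more calls
than dimensions; the cap is reported via `message()` and stored in the
result. Any fixed `dims` can be passed instead, and the choice is logged
in every output file.

Each (focal, other) pair, and each per-individual posterior fit, uses a
random stream derived deterministically from the run seed and the
individual ids, so overlap matrices are bit-reproducible and invariant to
the order in which individuals are supplied.

## Group comparisons

Per-individual WID, BID and aggregate ANO are compared between two
conditions with two-sided Wilcoxon rank-sum tests (`stats::wilcox.test`
defaults: exact when both n < 50 and tie-free, otherwise normal
approximation with continuity correction), summarised by medians and
type-7 interpolated quartiles, at a 0.05 significance threshold, one raw
p-value per metric with no multiplicity adjustment — matching the
reporting conventions of the analyses this package mirrors.

## The synthetic-data generator

`simulate_population()` draws each individual's mean call as a Gaussian
offset from a shared base contour (a rise–fall shape spanning roughly
630–1000 Hz, 0.35 s — the band and duration typical of little-owl
territorial calls) and each call as the mean plus independent Gaussian
within-individual noise; durations are floored at 0.05 s. Defaults are 22
individuals and 25 calls per individual — the sample sizes of the field
designs it stands in for — with sigma_b = 60 Hz and sigma_w = 35 Hz
(duration: 0.04 s and 0.025 s), a between/within ratio of about 1.7 that
produces HS, DS and overlap values in the range reported for strongly
individualised territorial calls. `contour_smoothness` mixes the
between-individual offsets through a small cosine basis (rescaled so the
marginal per-feature sd stays sigma_b) to mimic the smooth, correlated
way real pitch contours differ between individuals; the default (0,
independent offsets) is what the closed-form HS limit
`expected_hs()` $= \sum_f \tfrac12\log_2(1+\sigma_b^2/\sigma_w^2)$
assumes.

The generator matches the assumptions of the analysis model (Gaussian,
no call-level autocorrelation, stationary individuals) — deliberately, as
its job is parameter recovery and power analysis for the pipeline.
Passing tests on simulated data therefore shows the estimators do what
they claim under the model; it does not validate the model against real
recordings, which show non-Gaussian contour variation, octave errors,
recording-session effects and playback-provocation effects the generator
does not emulate.

## Numerical choices and problem sizes

* Flat tables are written at `%.17g` precision, so write–read round-trips
  are exact to the bit.
* PCA uses a full eigendecomposition of the sample covariance (all
  components retained even when rows < columns); negative eigenvalues
  from rounding are clamped at zero.
* Posterior covariance draws are obtained by inverting Wishart draws of
  the precision; Cholesky factors for sampling and Mahalanobis evaluation
  are cached per draw, and overlap evaluation is vectorised over draws,
  which is what makes replicated end-to-end studies affordable.
* Degenerate inputs: zero-variance features, zero within-individual
  variation (HS would be infinite), singular covariances, individuals
  with fewer than two calls, and empty samples are all explicit errors or
  warnings rather than silent NaNs; validation (`validate_call_table()`)
  flags out-of-band frequencies against the 500–2000 Hz plausibility band
  without mutating data.
* Test problem sizes were chosen to estimate each property with adequate
  Monte-Carlo resolution while keeping the default suite around a minute:
  null-DS calibration at 10 × 25 calls over 5 seeds; HS recovery at 20
  individuals with 25/100/400 calls over 20 seeds; the two-condition
  directional check over 50 replicates of the 14/10 × 25 design at 200
  posterior and 500 Monte-Carlo draws per pair (the directional contrast
  sits far from the decision boundary, so reduced draw counts do not
  limit it); exact Wilcoxon enumeration over all sample sizes up to 6;
  and a 10,000-replicate null rejection-rate check of the exact test.

## Known limitations

* HS comparisons across samples that differ strongly in individual count
  inherit the finite-$k$ effects discussed above; the package reports
  both HS variants but cannot decide which a given published number used.
* The niche model is Gaussian by construction; heavy-tailed or
  multi-modal callers (e.g. individuals with several call variants) will
  have their overlap underestimated or overestimated unpredictably.
* Manual screening of badly traced contours — part of any real workflow —
  is out of scope; only numeric validity and band checks are provided.
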