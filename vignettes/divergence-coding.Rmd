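---
title: "Divergence coding: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence coding: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divcode)
```

## The model

Divergence coding digitizes a continuous omics profile into a short alphabet
describing, feature by feature, how a sample deviates from a reference
population. Let $X = (X_j)$, $j = 1..m$, be one sample's profile. Every
sample is first mapped to quantile scale by a scaled rank transform,

$$Q_j(X) = \frac{|\{i : 0 < X_i \le X_j\}|}{|\{i : 0 < X_i\}|},$$

so that $Q_j \in [0,1]$, zeros map exactly to zero, and the largest positive
entry maps exactly to one. The transform is strictly per-sample — no pooling
across samples, no other normalization — which makes the coding comparable
across platforms whose raw scales differ, at the price of working with ranks
only (see *Limitations*).

Given $n$ baseline samples, the support of the baseline distribution for a
feature set $S$ (a single feature in the univariate case) is estimated from
$k$-nearest-neighbour spheres in $[0,1]^{|S|}$: with neighbourhood parameter
$\gamma \in (0,1)$ and $l = \max(1, \lfloor n\gamma \rfloor)$, each baseline
sample contributes a Euclidean sphere around its quantile sub-vector whose
radius is the distance to its $l$-th nearest *other* baseline sample. The
$1-\beta$ fraction of spheres with the largest radii is discarded as outliers,
and the support $\hat{U}^S$ is the union of the kept spheres. A new sample is
coded

$$Z(X)^S = \mathbf{1}\{Q(X)^S \notin \hat{U}^S\} \in \{0, 1\}.$$

Univariately the union of kept 1-D spheres is simplified to a single interval
from its lowest to its highest end (clamped to $[0,1]$), and the coding
becomes ternary: $-1$ below the interval, $+1$ above, $0$ inside, with
boundaries inclusive.

## Parameters and calibration

* **`gamma`** (neighbourhood size, unitless in $(0,1)$): radii grow with
  `gamma`, so larger values widen the support around each baseline point.
* **`beta`** (kept fraction, default 0.95): the trimming quantile. `beta = 1`
  keeps every sphere; every baseline point then lies in its own sphere and
  the in-sample divergence rate is exactly zero.
* **`alpha`** (budget, default 0.01): the target upper bound for the
  *achieved* baseline alpha — the average proportion of divergent features
  per baseline sample when the baseline is coded against its own fitted
  support. `divfit()` evaluates the candidate list
  `gamma in {0.01, ..., 0.09, 0.1, ..., 0.9}` in ascending order and keeps
  the first candidate whose achieved alpha is at or below the budget, i.e.
  the tightest support compatible with the budget.

Achieved alpha is computed in-sample (the baseline coded against the support
fitted on it), not leave-one-out: the support is an estimate of the
population's region, and the budget is a statement about how much of the
fitting cohort that region may exclude.

Two monotonicity facts matter for the search. At fixed `gamma`, increasing
`beta` keeps a superset of spheres of unchanged radii, so the support is
nested and alpha is non-increasing in `beta`. In `gamma` the situation is
subtler than it looks: each radius grows with `gamma`, but trimming keeps
spheres by the *rank* of their radius, and ranks re-order as the
neighbourhood size changes, so supports at different `gamma` need not nest
once `beta < 1`. Small increases of alpha in `gamma` do occur on real
fixtures. Alpha-monotonicity in `gamma` is exact at `beta = 1`, and in
practice the achieved alpha still trends strongly downward over the candidate
grid, so the ascending first-hit search is used as the calibration rule; its
result is reported (`GammaSearchResult`) with the per-candidate alpha map so
a non-monotone stretch is visible to the user.

Other defaults: at least 2 baseline samples are required and fewer than 20
draw a warning — radii are order statistics of within-cohort distances and
are unstable in very small cohorts. When `floor(n * gamma) = 0` the
neighbourhood is clamped to `l = 1` with a warning rather than failing.

## Downstream statistics

* `divergence_probability()`: per feature, the fraction of samples with a
  non-zero code.
* `sample_divergence_counts()`: per sample, the divergent-set size split
  into upper/lower — a simple sample-level deviation score.
* `chisq_divergence()`: per feature, a 2x2 divergent-vs-group table tested
  with the Yates-continuity-corrected chi-squared statistic (1 df),
  Bonferroni-adjusted by default. The correction term is
  $\min(0.5, |O - E|)$ per cell, matching the classical statistic; tables
  with a zero marginal are reported as statistic 0 / p 1 and flagged
  `degenerate` rather than erroring, because never-divergent features are
  common and are a result, not a failure.
* `co_divergence()` / `combine_codings()`: cross-modality co-divergence
  proportions for feature pairs (with concordant/discordant splits when both
  codings are ternary, concordant meaning both $+1$ or both $-1$), and the
  elementwise AND of two binary codings on their shared index.
* `gene_methylation_coding()`: CpGs mapped to one gene treated as one
  multivariate feature (binary coding) when there are at least two of them,
  binarized univariate coding for single-CpG genes. The quantile transform
  is applied to the full CpG matrix before any row subsetting, since ranks
  depend on the whole profile.
* `cluster_cpgs()` + `cluster_divergence_score()` +
  `cluster_permutation_pvalues()`: CpGs chained along each chromosome with
  adjacent gaps at most `max_gap` (default 300 bp, threshold inclusive,
  1-based inclusive `[start, end]` intervals), scored by
  $p_k = \sum_{j \in r_k} \sum_i |z_{i,j}| \,/\, (n\,|r_k|)$.

### Permutation null for cluster scores

The null distribution is built by permuting the CpG-to-profile assignment —
the cluster structure along the genome stays fixed while divergence profiles
are shuffled across CpGs — and recomputing all cluster scores. A score of a
30-member cluster has far smaller variance than a singleton's, so permuted
scores are pooled only across clusters of equal member count (size-stratified
null). P-values use the add-one rule $p = (1 + b)/(1 + B)$ with $b$ the
number of null scores in the stratum at or above the observed score, so $p$
is never zero at finite permutation count; ties count against significance.
One integer seed drives the entire permutation sequence and is recorded in
the output; the session RNG state is restored afterwards.

## What the synthetic generator emulates — and what it does not

`simulate_cohorts()` provides matched baseline/case matrices with known
ground truth.

*Expression-like mode* draws feature log-means from $N(\mu, \tau)$
(defaults $\mu = 3$, $\tau = 2$, a dynamic range of roughly 11 log2 units
across features) and entries from a log-normal with within-feature log-SD
$\sigma = 0.4$, far smaller than $\tau$ — as in real RNA-seq, where a gene's
between-sample variability is small against the between-gene dynamic range;
this is what keeps within-sample ranks stable enough to code against.
Dropout is tied to expression level (zero probability decreasing with
log-mean, cohort average `zero_inflation = 0.25`), concentrating the zero
mass in lowly expressed features. The planted effect is a displacement on
the quantile scale, the scale the coding operates on: a planted feature at
percentile $q_0$ of the log-mean distribution has its case log-mean moved to
percentile $q_0 + \delta$ (`effect_size`, default 0.5 — a large effect,
roughly a 3 log2-unit fold change for a mid-range feature). Planting is
restricted to features with enough rank headroom to express the full shift:
a feature already at the top of the ranking cannot move further up, and with
zero inflation the baseline interval's lower end is typically 0, which masks
downward shifts of lowly expressed features — hence the `"up"` default
direction for expression.

*Methylation-like mode* draws beta values from hypo-/hyper-methylated
`Beta(2, 18)` / `Beta(18, 2)` feature states; planted shifts act directly on
the beta scale and are clipped to $[0,1]$ with a warning. The optional
`epimutation_rate` redraws each case entry uniformly on $[0,1]$ with that
probability, independently across CpGs — a diffuse, exchangeable
methylation instability with no regional signal. The permutation-null
calibration study uses `epimutation_rate = 0.25` (diffuse tumour
hypomethylation affects on the order of 20–30% of the methylome): under a
drift-free null a coding calibrated to `alpha = 0.01` diverges almost
nowhere, cluster scores are nearly all exactly zero, and permutation
p-values degenerate at 1 — exchangeability, not absence of divergence, is
the null the permutation machinery tests.

The generator deliberately does **not** mimic gene–gene correlation,
batch effects, real identifiers, or count noise; features are independent
given their parameters. Passing the recovery and calibration studies
therefore shows the estimator and its statistics behave as designed under
controlled conditions — not that effect sizes of real cohorts are
recoverable at these rates.

### Study sizes

The bundled studies use sizes chosen to exercise every code path while
keeping the whole validation quick on a laptop: 200 features with 50 + 50
samples and 20 planted features for recovery; 500 CpGs, 40 + 40 samples and
200 permutations for calibration; oracle-equivalence checks run on 100
random instances with $m \le 20$, $n \le 15$, $|S| \le 5$. At these sizes
the full test suite and the acceptance script each finish in well under a
minute.

## Numerical choices and degenerate inputs

* Quantiles of radii use R's default linear interpolation (type 7); at
  least one sphere is always kept; radius ties at the trimming threshold are
  kept (`<=`).
* Interval and sphere boundaries are inclusive: a value exactly at an
  interval endpoint, or a point exactly on a kept sphere's surface, codes 0.
* Missing raw values propagate as missing quantiles and are excluded from
  both counts of the rank transform; an all-zero column transforms to all
  zeros rather than erroring.
* Distances are Euclidean in quantile space; the nearest-neighbour count
  excludes the sample itself (otherwise every $l$-th neighbour distance
  would be deflated by the self-distance 0).
* An empty feature-set collection yields a 0-row coding with sample ids
  preserved; sets with unresolvable members are reduced (warning) or
  skipped (warning), and model/case feature matching intersects by id,
  preserving model order.
* A case cohort is auto-transformed unless `transformed = TRUE`; a matrix
  declared transformed must already lie in $[0,1]$.

## Limitations

* Ranks saturate: a feature near the top of the within-sample ranking
  cannot diverge upward (its interval upper end is at or near 1), and the
  zero floor hides downward shifts of features with substantial dropout.
* The coding is compositional: strongly shifting one subset of features
  displaces the ranks of the rest, so a large injected signal inflates
  apparent divergence of null features — visible in the recovery study as
  null probabilities somewhat above the achieved baseline alpha.
* The trimming quantile makes the achieved alpha a step-like function of
  `gamma` that is not guaranteed monotone (see above); the reported
  per-candidate alpha map is the audit trail.
* Cluster p-values are valid for the exchangeable-CpG null; CpGs are not
  exchangeable in real methylomes (island structure correlates with
  divergence rates), so they rank regions rather than test a biological
  null exactly.
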