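---
title: "Quantifying climatic niche shifts and reciprocal transferability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying climatic niche shifts and reciprocal transferability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheshift)
```

# The question

When a species invades a new region, does it occupy the same climatic
conditions as in its native range (niche conservatism), or has the realized
niche shifted? `nicheshift` implements the two standard, complementary ways
of answering this for presence-only data:

1. **Environmental-space niche quantification**: compare kernel-smoothed,
   availability-corrected occupancy surfaces of the two ranges in a shared
   2-D ordination of climate, with overlap statistics, permutation tests,
   and the expansion/stability/unfilling decomposition.
2. **Reciprocal distribution modelling**: fit a presence-background maximum
   entropy model in each range, project it onto the other, and measure how
   badly skill transfers (AUC, continuous Boyce index, TSS).

Everything runs end-to-end on synthetic paired-range data generated by the
package itself, so the whole pipeline is testable without downloads.

# Niche quantification in environmental space

## The shared ordination

Both ranges' *available* environments (all accessible raster cells, or any
background sample) are pooled, z-score standardized, and ordinated by PCA;
the first two axes define the niche space. Fitting the ordination on the
pooled backgrounds of *both* ranges — never on occurrences — is what makes
cells of the two occupancy grids comparable. `fit_pca_env()` fixes axis
signs deterministically (largest loading positive), and `project_env()`
maps any environment matrix into the space.

## Occupancy grids

For each range, `build_niche_grid()` lays an `R` x `R` grid (default
`R = 100`) over the pooled background extent (no margin; points outside are
clamped to the boundary cell — they can only arise for occurrences, since
the backgrounds define the bounds) and estimates two product-Gaussian
kernel densities at the cell centers: the occurrence density `o` and the
availability density `e`. The availability-corrected occupancy is
`z = o / e` on available cells, normalized to sum to one; `z_uncor = o /
max(o)` is kept for sensitivity analyses. Each density is smoothed with
Silverman's rule computed per axis on its *own* data, times a configurable
multiplier — the occurrence surface should not inherit its smoothness from
the much larger background sample, and fixing the availability bandwidth
independently lets permutation tests hold `e` fixed while only occurrence
surfaces are rebuilt.

**Numerical support.** A Gaussian kernel density is positive almost
everywhere, which creates two artifacts if taken literally. First, the
ratio `o / e` explodes on cells whose availability is only a distant
kernel tail — environments that do not actually exist in the range. We
therefore truncate `e` below the smallest smoothed density observed at an
actual background point: a data-driven support estimate, in the spirit of
thresholding a kernel home-range at the least dense observed location.
Second, an "occupied cell set" defined as `z > 0` would cover the entire
support regardless of where the species is; `niche_dynamics()` instead
defines occupancy as cells whose `z` is at least the `quantile_threshold`
quantile (default 0 = the minimum) of `z` over the cells actually holding
occurrences. Both choices reduce smoothly to the naive definitions as the
bandwidth shrinks.

## Overlap, equivalency, similarity, dynamics

Schoener's `D = 1 - 0.5 * sum(|z1 - z2|)` and Warren's Hellinger-based
`I = 1 - 0.5 * sum((sqrt(z1) - sqrt(z2))^2)` measure overlap on the
normalized surfaces; both are 1 on identical niches and 0 on disjoint
support.

The **equivalency test** pools the occurrence scores of both ranges and
re-splits them at random (keeping the original sample sizes), rebuilding
the occupancy surfaces against each range's original availability. The
p-value is lower-tailed, `(count(null <= observed) + 1) / (n_reps + 1)`:
equivalency is rejected when the observed overlap is smaller than random
relabelling produces. A 95%-CI rejection flag is also emitted. The fitted
ordination, grid bounds and the two availability surfaces are reused
across repetitions; only occurrence densities are rebuilt — this is both
standard practice and what makes 1,000 repetitions tractable.

The **similarity test** relocates the whole occupancy surface of one range
to a random center drawn from that range's available environmental cells
(translation clipped to the grid and renormalized; a toroidal `wrap`
variant is available, under which a uniform surface is exactly invariant).
The p-value is upper-tailed: a small value means the two niches are more
similar than a randomly placed niche of the same shape. Both directions
are computed, as in the usual paired presentation.

**Dynamics.** With occupied sets `N` (native) and `V` (invasive) as above,
expansion is the share of invasive occupancy mass outside `N`, stability
its complement (`E + S = 1` by construction), and unfilling the share of
native occupancy mass outside `V`. An `analogue_only` switch restricts all
sums to cells available in both ranges; it is off by default, and the
choice matters exactly when the two ranges' climates barely overlap.

# The maximum entropy model

`fit_maxent()` estimates the Gibbs distribution over the background cells,
`p(x) proportional to exp(lambda . f(x))`, that maximizes entropy subject to
L1-relaxed constraints tying fitted feature expectations to presence
feature means — equivalently, it minimizes the convex objective

```
-mean_presence(lambda . f) + log Z_bg(lambda) + sum_j beta_j |lambda_j|
```

Feature classes follow the conventional alphabet — linear, quadratic,
product, hinge (forward and reverse), threshold — built by
`build_features()` on variables rescaled to [0, 1] by their background
range; projection beyond the training range clamps ("clamping"). Hinge and
threshold knots are placed at `knots` (default 20) evenly spaced positions
per variable: deterministic and size-independent, unlike the data-driven
knot placement of the reference Java implementation, which we deliberately
do not replicate.

Penalties are `beta_j = RM * base(class_j) * sd_j / sqrt(n_presence)` with
base constants L = Q = P = T = 1 and H = 0.5 (`maxent_penalties()`), where
`sd_j` is the feature's background standard deviation — penalties
proportional to feature scale are what published maxent defaults use, and
rescaled features compress mean differences enough that unscaled penalties
would annihilate all signal at realistic sample sizes.

The solver is proximal coordinate descent: each coordinate takes an exact
soft-thresholded Newton step under the current Gibbs weights, with an
objective-decrease safeguard, cycling an active set with periodic full
sweeps; convergence is declared when every coefficient's KKT box condition
holds within `tol` (default 1e-7; iteration cap 10,000 sweeps). The
objective is convex, so restarts land on the same optimum; the tests
assert the KKT conditions, normalization of raw output, and that model
complexity is non-increasing along the regularization path.

Predictions: `raw` is the Gibbs probability normalized over the training
background; `cloglog = 1 - exp(-exp(H) * raw)` with `H` the entropy of the
fitted distribution — the standard transform to a 0-1 occurrence
probability scale. AICc uses `k` = nonzero coefficients and the presence
log-likelihood under the training-background normalization; candidates
with `n <= k + 1` are flagged invalid. `tune_maxent()` crosses the six
conventional feature-class combinations (L, H, LQ, LQH, LQHP, LQHPT) with
regularization multipliers 0.5-4.0 in steps of 0.5 — 48 candidates —
selecting the lowest-AICc valid candidate (ties: fewer coefficients, then
smaller multiplier), optionally with 4-fold spatial-block AUC
cross-validation (`block_partition()`: median-latitude split, then
median-longitude within each half).

# Evaluation metrics

`eval_auc()` is the rank (Mann-Whitney) estimate with ties counted one
half. `boyce_index()` slides 101 overlapping windows of width 10% of the
score range (both configurable) and returns the Spearman correlation
between window midpoint and the presence-to-background frequency ratio;
windows without background are skipped and fewer than three valid windows
is an error. `tss_stat()` treats background as pseudo-absence and scans
all score midpoints for the threshold maximizing sensitivity +
specificity - 1; `reciprocal_report()` reports TSS both with the threshold
optimized in the evaluation range and with the threshold *transferred*
from the training range's local evaluation — the transferred variant is
the one that can go strongly negative when a model is projected onto a
shifted range, and is how a "counter-prediction" signature arises in
cross-range tables.

# The synthetic paired-range generator

`make_scenario()` builds two independent landscapes (100 x 100 cells by
default, 30 arc-second cell size, 3-cell masked border), each with four
climate-like layers: smooth random fields (sums of low-frequency cosine
components, at most 3 cycles per extent by default), orthonormalized over
cells and mixed by the Cholesky factor of a target correlation matrix, so
sample correlations hit the target exactly before masking. The default
target correlates the first pair at 0.6 and the second pair at 0.5
(near-zero across pairs) — a temperature-like and a precipitation-like
block, emulating a typical post-collinearity-filter variable set.

The species has an isotropic Gaussian niche in climate space with sd
`sigma = 0.5` (standardized climate units), centered by default at -0.5 on
every variable. The centroid is deliberately *not* at the climate mode: a
species whose niche coincides with the most common available environment
gives a distribution model no presence-background contrast, which is a
degenerate study condition rather than a realistic one. Occurrence cells
are drawn with probability proportional to Gaussian suitability and
jittered within the cell; defaults are 79 native and 6,579 invasive
occurrences, mirroring the kind of strong sample-size asymmetry real
native/invasive datasets show. The invasive centroid is displaced by
`delta` along a configurable unit direction; the analytic Bhattacharyya
coefficient `exp(-delta^2 / (8 sigma^2))` is recorded as ground truth.

A `shared_landscape` switch reuses one landscape realization for both
ranges. With `delta = 0` this makes the two occurrence sets exactly
exchangeable — the clean null for checking the equivalency test's type-I
error — whereas independently drawn landscapes leave availability
differences between ranges and only approximate exchangeability.

What the generator does *not* emulate: spatial sampling bias, dispersal
limitation, biotic interactions, temporal dynamics, and non-Gaussian
(multi-modal or asymmetric) niches. Passing tests on these scenarios
therefore demonstrate correctness of the estimators and the qualitative
behaviour of the pipeline, not robustness to the observational artifacts
of real occurrence data.

# Problem sizes and numerical choices

The test-suite defaults are deliberate: niche grids at `R = 100` except
where an oracle needs a small grid (`R = 25`); permutation tests at 99
repetitions in simulations and 1,000 in full analyses; calibration checks
over 200 null scenarios at reduced sample sizes (50/200); tuning exercises
the full 48-candidate grid with a 2,000-2,500-point background. Degenerate
inputs are handled explicitly: zero-variance variables are dropped with a
reason, constant variables lose their nonlinear features, empty masks,
empty occupied sets and degenerate score ranges are errors, and
rarefaction keeps the first point per cell in input order so reruns are
stable. All randomness flows through explicit integer seeds; named
sub-streams are derived from one root seed so that background sampling,
permutation tests and the generator never share a stream.

# Known limitations

- Rasters are exchanged as ESRI ASCII grids; there is no GeoTIFF reader in
  this package, and grids are treated as plain lon/lat arrays (no
  projection handling beyond the half-open cell convention).
- The availability-support and occupancy-threshold rules above are
  bandwidth-dependent; with very small occurrence samples (< ~20) the
  data-driven support is noisy and E/S/U should be read qualitatively.
- The equivalency test conditions on the fitted ordination and bounds;
  uncertainty in the PCA itself is not propagated.
- AICc for presence-background models is a heuristic (the likelihood is
  normalized over the background sample); it is used for model ranking,
  as is conventional, not as an absolute goodness measure.
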