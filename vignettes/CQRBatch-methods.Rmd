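---
title: "CQRBatch: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CQRBatch: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(CQRBatch)
```

# Scope

CQRBatch removes batch effects from OTU count tables in two stages:
a negative binomial (NB) stage for *systematic* effects (a constant
per-batch shift of each OTU's mean) and a zero-inflated composite
quantile regression (CQR) stage for *nonsystematic* effects (batch
differences in spread, tails and zero rates). This vignette documents
the models, every tunable that matters, the numerical choices, and
what the validation on synthetic data does and does not establish.

# Stage 1: negative binomial adjustment

For each OTU `j`, the non-zero counts are modelled as
`Y | Y>0 ~ NB(mu, theta)` with

    log(mu_ijg) = sigma_j + X_i' beta_j + gamma_jg + log N_i,

where `N_i` is the sample's total read count (all OTUs), entering as a
fixed offset, and the NB variance is `mu + theta mu^2` (`theta -> 0`
is the Poisson limit). The model is deliberately fitted on non-zero
counts only: zeros are handled by the stage-2 presence model, and a
zero-inflated likelihood here would double-count them.

**Identifiability of `gamma`.** With a full set of batch effects the
intercept is confounded; we impose the sample-size-weighted
sum-to-zero constraint `sum_g n_g gamma_jg = 0` (weights are the
non-zero counts per batch), so the "batch-free" mean
`log(mu*) = log(mu) - gamma_g` sits at the weighted grand mean and the
overall abundance scale is stable.

A second, subtler identifiability point: because the offset is the
*realised* total library size, a batch shift shared by every OTU in
the same direction inflates the library totals themselves and is
absorbed into the offset. Stage 1 therefore identifies and removes
*composition-level* batch shifts — each OTU's deviation from the
library-wide batch effect. The remaining library-scale component is a
per-batch distributional difference, which is exactly what stage 2's
quantile transport removes (its models carry no library offset). The
parameter-recovery tests consequently evaluate the NB estimator
against the generative offsets recorded by the simulator.

**Dispersion.** The mean structure is fitted by maximum likelihood
(`MASS::glm.nb`, single dispersion); per-batch dispersions `theta_jg`
are then re-estimated by method of moments within each batch, solving
`Var = mu + theta mu^2` on the squared residuals, floored at `1e-4`
and capped at `1e4`. The pooled dispersion is the arithmetic mean
`theta_j* = mean_g(theta_jg)`. If the NB fit fails to converge the OTU
falls back to a Poisson fit with `theta = 1e-4` and is flagged; if the
design is singular on the non-zero subset the OTU is passed through
uncorrected and flagged.

**Quantile mapping.** Each non-zero count moves from
`NB(mu_ijg, theta_jg)` to `NB(mu_ij*, theta_j*)`, both truncated to
the positive support, by matching the midpoint CDF level
`p = (F(y-1) + F(y)) / 2`. The midpoint rule is deterministic (no
randomised quantile residuals); levels are computed in survival
(upper-tail) space so that large counts keep full floating-point
precision instead of saturating at CDF 1. The mapped value is the
smallest positive integer whose truncated target CDF reaches `p`; the
map is monotone and is the exact identity when source and target
coincide.

# Stage 2: zero-inflated composite quantile regression

On the stage-1 table, per OTU:

1. **Presence model.** `logit Pr(Y* > 0) = c + X' zeta + B' psi`,
   with batch reference-coded against the reference batch. A ridge
   penalty (`lambda = 1e-4` on non-intercept terms) keeps
   quasi-separated fits finite — common for sparse OTUs — and fitted
   probabilities are clamped to `[1e-6, 1 - 1e-6]`. All-zero /
   all-non-zero OTUs get the clamp values directly, flagged. Although
   the batch term can be read as a random effect, a per-sample random
   effect is not identifiable in a Bernoulli model; the fixed-effect
   reading matches the linear predictor form and is what we implement.

2. **Composite quantile regression.** Conditional quantiles of the
   non-zero values over the grid `tau_s = s/(k+1)`, default `k = 19`
   (the 5th...95th percentiles):
   `Q(tau_s) = b_s + X' alpha + B' delta`. The default (`composite`)
   shares `alpha, delta` across the grid, minimising the summed check
   loss; `mode = "per_tau"` fits each level independently for data
   whose covariate effects genuinely change across quantiles. With
   fewer observations than `covariates + batches + k`, or on solver
   failure, the OTU falls back to per-batch empirical quantiles,
   flagged.

3. **Transport.** The sample's own-context zero-inflated quantile
   function (presence probability and quantile predictions under its
   own batch) assigns the observed value a level `tau_obs`; the value
   is re-materialised under the reference context (same covariates,
   batch indicators swapped to the reference — keeping `X` fixed is
   what preserves biological signal). Zeros take the midpoint of the
   zero mass, `tau_obs = (1-q)/2` (optionally uniform over the zero
   mass with `stochasticZeros`); positive values take the midpoint of
   their preimage interval under the piecewise-linear positive branch,
   inverted analytically. Outputs are rounded half-to-even to
   non-negative integers so the corrected table remains a valid count
   table. Reference-batch samples pass through unchanged.

**Numerical choices in the CQR optimiser.** No linear programming
solver is assumed; the composite objective is minimised by a
majorise-minimise scheme (smoothed iteratively reweighted least
squares) with a decreasing smoothing parameter (`1e-1` down to
`1e-9`), an exact per-tau intercept reset each sweep (given the
slopes, the optimal intercepts are residual quantiles, taken as
type-1 empirical quantiles), and a monotonicity safeguard on the true
check-loss objective with relative tolerance `1e-7`. Intercept-only
problems are therefore solved exactly; with slopes the attained
objective agrees with an exact LP solution to about `1e-5` relative,
which the test suite asserts against an independent quantile
regression oracle.

**Quantile crossing** is resolved by monotone rearrangement: per
sample and context, the predicted grid values are sorted in `tau`
before interpolation, and floored at the OTU's smallest observed
positive value. Between grid levels the quantile function is
piecewise-linear.

**Out-of-grid values.** Below the 5th or above the 95th grid
percentile the quantile level is not identified. Such values are
transported by preserving their additive offset from the transported
grid edge. This keeps the map monotone in the observed value and an
exact identity when the two contexts coincide; a hard clamp to the
edge level would compress the tails even in the no-batch-effect case.
One consequence: monotonicity is guaranteed among positive values,
while an observed zero (which travels by its level) can in contrived
configurations land above a barely-positive value; the tests assert
the positive-branch guarantee.

# Reference batch selection

Batches are screened for homogeneity: for every ordered batch pair and
every correctable OTU, a two-group Kruskal-Wallis test on relative
abundances (count / library size, zeros included); a batch's
homogeneity is the fraction of its comparisons with `p >= alpha`
(default `alpha = 0.05`). This is a screening heuristic, not
inference, so no multiplicity correction is applied. Batches at or
above the median homogeneity are shortlisted (`top_half`; a fixed
threshold rule is available). Among the shortlist, each batch's
dispersion is summarised by the robust coefficient of variation
`100 * MAD / median` — MAD without the 1.4826 normal-consistency
factor, i.e. the plain ratio — computed per OTU on the batch's
*non-zero* counts (medians of mostly-zero vectors are 0, which makes
the ratio undefined; OTUs with fewer than 3 non-zero values in a batch
are skipped) and aggregated by the median across OTUs. Lowest robust
CV wins; ties break to the larger batch, then lexicographically. The
choice can always be overridden (`reference = "<label>"` or
`force =` in `selectReference()`).

The scale on which the homogeneity screen operates (relative
abundances) and the batch-level aggregation of per-OTU tests are
design decisions of this package: a batch-level ranking requires
pairwise aggregation, and relative abundances make batches of
different sequencing depth comparable.

# The synthetic-data generator

`simulateCounts()` draws library sizes log-normally (default
`log N ~ Normal(log 2e4, 0.5)`), one standard-normal and one
Bernoulli(0.5) covariate, per-OTU baselines
`sigma_j ~ U(-9, -4)` (log relative abundance), and generates counts
from `NB(mu, theta_g)` with `log mu` following the stage-1 model;
structural zeros are imposed afterwards with probability `1 - q_ij`
from the stage-2 presence model (per-OTU intercepts
`z0_j ~ U(0.1, 2.1)`, defaults `zeta = (0.3, -0.3)`). Zeroing after NB
sampling produces both sampling and structural zeros, as in real
data. Per-OTU batch shifts can be jittered around the study-level
`gamma` (`gammaOTUSd`), which matters for the Aitchison metric: a
shift common to all OTUs cancels under CLR.

The default presence intercept range was calibrated once so that the
presets' overall zero fraction lands near 31%, the zero-inflation
regime in which quantile-based correction is most stable; higher zero
fractions thin the non-zero sample available to the extreme grid
levels and destabilise them.

Two presets emulate real multi-study designs: `hivrc_like` (4 batches
of 232/43/23/62 samples) and `mouth_like` (7 plates of
43/49/56/79/89/88/91), both with 200 OTUs, batch-specific dispersions
and zero-rate distortions.

**What passing on synthetic data shows — and what it does not.** The
generator matches the model family the method assumes (ZINB with
log-linear covariate and batch effects), so recovery and
batch-reduction results on it validate the estimators and the
plumbing, not the model's adequacy for any particular real data set.
It does not emulate phylogenetic correlation between OTUs,
compositional closure, or covariate-batch confounding; in confounded
designs the transport can remove biology along with batch, and no
correction method can separate the two without design information.

# Evaluation suite

Four dissimilarities (on raw counts; a `relative` switch is
available): Bray-Curtis `sum|x-y| / sum(x+y)`; Manhattan `sum|x-y|`;
Canberra as the unscaled sum of `|x-y|/(x+y)` over coordinates with
`x+y > 0` (coordinates zero in both samples are skipped without
rescaling — note that both `stats::dist` and `vegan::vegdist` rescale,
so this is computed directly); Aitchison as Euclidean distance of CLR
coordinates with pseudocount 0.5 (exposed as a parameter). PERMANOVA
R² uses the one-factor Gower decomposition
(`R² = 1 - SS_within/SS_total` on squared distances) with label
permutations for the p-value (default 999, seeded); it matches
`vegan::adonis2` to near machine precision and a one-way ANOVA
decomposition exactly for Euclidean 1-D data. PCoA is classical MDS
(`stats::cmdscale`), with negative eigenvalues dropped and reported.
Average silhouette uses `(b - a)/max(a, b)` with singleton clusters
scoring 0.

# Problem sizes and runtimes

The test suite validates oracle equivalence on tiny instances (<= 6
points, tolerance `1e-10`), the quantile map against pmf enumeration
(y = 1..200, 100 random parameter pairs, exact), parameter recovery at
2 x 500 samples (NB; `gamma` within 0.1, pooled `theta` within 30%)
and n = 2000 (presence model, coefficients within 0.1), end-to-end
batch-effect reduction on the `hivrc_like` preset (360 samples, 200
OTUs; about a minute), and null safety across 20 small replicates (2 x
40 samples, 40 OTUs: correction must not systematically inflate
PERMANOVA R² when no batch effect exists). These sizes keep the full
suite to a few minutes while leaving the estimators' error well inside
the asserted bounds.

# Known limitations

- Extreme-quantile instability under heavy zero-inflation: with few
  non-zero values the 5th/95th grid levels rest on a handful of order
  statistics. The prevalence filter (default: overall prevalence
  >= 0.1 and >= 3 non-zero samples per batch) excludes OTUs where the
  fits would be ill-posed; excluded OTUs pass through uncorrected and
  are flagged.
- The NB family may not fit all real count data; stage 1 is only as
  good as the mean-variance law it assumes. `mode = "per_tau"`
  relaxes the shared-coefficient assumption of stage 2 when effects
  differ visibly across quantiles.
- One-factor PERMANOVA (batch only) matches the intended evaluation;
  covariate-adjusted PERMANOVA is out of scope.
- The reference-batch transport inherits the usual caveat: if the
  reference batch represents the study poorly, aligning everything to
  it can distort rather than correct.
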