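# CQRBatch

Batch effect correction for microbiome OTU count tables, built for the
realities of 16S/metagenomic count data: heavy zero-inflation,
over-dispersion, unequal library sizes, and batches (studies, plates,
sequencing runs) of very different sizes.

Multi-batch microbiome studies routinely show stronger clustering by
batch than by biology. Corrections developed for microarray/RNA-seq
data assume (log-)Gaussian or pure NB responses and only remove
*systematic* effects — the constant per-batch mean shift. Count
distributions can also differ between batches in spread, tail weight
and zero rate (*nonsystematic* effects), which a mean shift cannot fix.
CQRBatch addresses both, in two stages.

## The model

Counts are `Y_ijg` for OTU `j`, sample `i`, batch `g`, with covariates
`X_i` and library size `N_i`.

**Stage 1 — systematic effects (negative binomial).** Non-zero counts
are modelled per OTU as `Y | Y>0 ~ NB(mu_ijg, theta_jg)` with

```
log(mu_ijg) = sigma_j + X_i' beta_j + gamma_jg + log N_i
Var(Y | Y>0) = mu + theta * mu^2
```

The batch term is removed on the log scale,
`log(mu_ij*) = log(mu_ijg) - gamma_jg` (with a sample-size-weighted
sum-to-zero constraint on `gamma_jg`), and dispersions are pooled,
`theta_j* = mean_g(theta_jg)`. Each non-zero count is then mapped from
its fitted truncated NB onto the batch-free truncated NB by matching
quantile levels. Zeros are untouched by stage 1.

**Stage 2 — nonsystematic effects (zero-inflated composite quantile
regression).** On the stage-1 table, a logistic model gives each
sample's presence probability
`q_ij = expit(X_i' zeta + B_i' psi)`, and composite quantile
regression models the non-zero conditional quantiles
`Q(tau | X, B) = b(tau) + X_i' alpha + B_i' delta` over the grid
`tau = s/20, s = 1..19`, with coefficients shared across the grid
(the composite objective sums the check loss
`rho_tau(u) = u(tau - 1{u<0})` over all grid levels). Presence and
quantile models combine into the zero-inflated quantile function

```
Qc(tau) = 0                          for tau <  1 - q
Qc(tau) = Q((tau - (1 - q)) / q)     for tau >= 1 - q
```

Every sample is transported onto a **reference batch**: its observed
value becomes a quantile level under its own batch's `Qc`, and is
re-materialised under the reference batch's `Qc` with the same
covariates. The reference batch is chosen data-driven: batches are
screened for distributional homogeneity with per-OTU Kruskal-Wallis
tests, and among the shortlist the batch with the lowest robust
coefficient of variation (`100 * MAD / median`) wins.

**Evaluation.** PERMANOVA R² (adonis-type, with permutation p), 2-axis
PCoA, and batch-labelled average silhouette, over Bray-Curtis,
Aitchison (CLR), Canberra and Manhattan dissimilarities. Good
correction shows smaller R² and silhouettes near zero.

A ground-truth ZINB simulator (`simConfig()` / `simulateCounts()`)
generates validation data with known `gamma`, `theta`, `zeta`, `psi`,
including presets mimicking real multi-study designs.

## Worked example

```r
library(CQRBatch)

cfg <- simConfig(nPerBatch = c(30, 30), m = 30, gamma = c(0.8, -0.8),
                 theta = c(0.3, 0.6), psi = c(0.3, -0.3), seed = 11)
sim <- simulateBatchExperiment(cfg)
sim$experiment
#> BatchCountExperiment: 30 OTUs x 60 samples
#>   batches: batch1(30) batch2(30)
#>   covariates: x1, x2
#>   reference batch: (unset)
#>   zero fraction: 31.2%; library sizes 92-7467

res <- correctBatchEffects(sim$experiment, seed = 11)
res
#> BatchCorrection: 30 OTUs x 60 samples
#>   reference batch: batch2
#>   corrected OTUs: 30 of 30
#>   stage-1 NB fits converged: 30 of 30
#>   mode: composite | quantile grid k = 19

ev <- evaluateCorrection(res@input, correctedExperiment(res),
                         nPerm = 999, seed = 11)
print(ev$summary, digits = 2)
#>        metric R2.before R2.after p.before p.after silhouette.before silhouette.after
#> 1 bray_curtis     0.198   0.0620    0.001   0.001            0.1777           0.0532
#> 2   aitchison     0.017   0.0028    0.474   1.000            0.0059          -0.0071
#> 3    canberra     0.153   0.0468    0.001   0.001            0.1237           0.0328
#> 4   manhattan     0.247   0.0340    0.001   0.068            0.2490           0.0658
```

The simulated two-batch table starts with strong batch structure
(Bray-Curtis PERMANOVA R² = 0.20, p = 0.001: a fifth of the
between-sample variation is explained by batch). After correction R²
drops to 0.06 and the average silhouette falls from 0.18 towards 0 —
batches are no longer separable — while covariate signal (`x1`, `x2`)
is preserved by construction of the counterfactual transport.

File-based workflows use `runPipeline()` / `runConfig()` (YAML
config), or the CLI wrapper:

```sh
Rscript inst/scripts/cqrbatch.R run --counts counts.tsv \
    --metadata meta.tsv --batch-column plate --covariates age,sex \
    --reference auto --seed 1 --out results/
```

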