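# kinmtl

Multi-task bilinear metric learning for facial kinship verification.

Kinship verification decides whether two face images show a parent and
their child. Public benchmarks label pairs with one of four kinship types
— father–son (FS), father–daughter (FD), mother–son (MS), mother–daughter
(MD) — and the conventional approach trains one verifier per type from
that type's pairs alone. Labeled kin pairs are scarce, and this per-type
isolation discards what heritable facial traits guarantee: the four types
are statistically related. `kinmtl` is for researchers studying metric
learning on small heritable-phenotype pair data who want a complete,
reproducible implementation of the correlated multi-task alternative,
including its baselines and its evaluation machinery.

## The model

Each type `v` scores a parent descriptor `p` against a child descriptor
`c` with a bilinear similarity that decomposes into shared and
type-specific structure:

    S_v(p, c) = pᵀ (W₀ + W*_v) c

Which auxiliary types to couple with a target, and how strongly, is
learned from the data:

1. **Correlation discovery.** For every type, fit an SVDD (RBF one-class
   boundary) to the absolute difference vectors |p − c| of its positive
   pairs; the correlation between two types is the Euclidean distance
   between their centroids (smaller = stronger). The K nearest types join
   the target, with initial simplex weights from reciprocal correlations.
2. **Joint training.** Minimize
   `Σ_v ( β_v Σ_i hinge(y_vi, S_v) + λ/2 ||W*_v||²_F ) + η/2 ||W₀||²_F`
   subject to `Σ β_v = 1, 0 < β_v < 1`, by alternating stochastic
   sub-gradient steps: one sampled pair per task updates W₀ and the W*_v,
   then a full-batch Lagrangian step updates the weights β.
3. **Decision.** A linear SVM on the scalar similarity score calls each
   test pair kin / not-kin; accuracy is reported under a leakage-free
   5-fold protocol.

Also included: the isolated single-task baseline, SVDD outlier filtering
(`isolated_svdd`), block-LBP (4096-d) and dense upright SIFT (6272-d)
descriptors with PCA, label-noise robustness sweeps, K sweeps, and a
seeded synthetic generator that plants shared-plus-specific kin maps with
controllable inter-type correlation so every claim is testable without any
image download.

## Worked example

```r
library(kinmtl)

gen <- generate_tasks(synth_spec(seed = 1))   # four synthetic kinship tasks
cfg <- train_config(seed = 1)

fit <- train_ccmtl(gen$tasks$FS, unname(gen$tasks[c("FD", "MS", "MD")]), cfg)
fit$profile
#> correlation_profile: target FS
#>   r: FD=0.3367, MS=0.287, MD=0.3721
#>   U: MS < FD
#>   beta0: FS=1, MS=3.48e-06, FD=2.97e-06

cross_validate(gen$tasks, "FS", "ccmtl", cfg)
#> eval_report [ccmtl on FS]: mean accuracy 0.785 (folds: 0.863 0.812 0.750 0.775 0.725), AUC 0.888
cross_validate(gen$tasks, "FS", "isolated", cfg)
#> eval_report [isolated on FS]: mean accuracy 0.740 (folds: 0.662 0.775 0.688 0.725 0.850), AUC 0.822
```

The correlation step ranks MS and FD as the two types most correlated with
FS on this draw and couples them (`K = 2` by default); the jointly trained
metric verifies held-out FS pairs at 78.5% against 74.0% for the isolated
baseline on identical folds. `k_sweep()` and `noise_sweep()` reproduce the
corresponding parameter and robustness experiments; see the methods
vignette (`vignettes/ccmtl-methods.Rmd`) for the model's assumptions,
every tunable parameter, and what the synthetic benchmark does and does
not emulate.

A thin CLI over the same functions lives at `inst/scripts/kinmtl.R`
(subcommands `synth`, `features`, `train`, `evaluate`, `sweep-k`,
`noise`).

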