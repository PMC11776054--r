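# ligandpath

Classify gas-molecule unbinding trajectories from [NiFe] hydrogenase MD
simulations into tunnel pathways.

[NiFe] hydrogenases catalyze H2 ⇌ 2H⁺ + 2e⁻ at an active site buried
deep in the protein; H2, CO and O2 travel between the site and the surface
through a network of gas tunnels (T1-T9 in the reference enzyme, plus a
T10 seen only in a homolog). Which tunnel a ligand takes matters for
engineering O2/CO-tolerant enzymes, but assigning pathways to hundreds of
simulated unbinding events by eye does not scale. `ligandpath` does the
assignment with supervised classifiers over a simple, robust trajectory
fingerprint, and ships a synthetic trajectory generator so the entire
pipeline is testable without any simulation data.

## Method at a glance

**Features.** For residue *r*, the contact fraction is

> x_r = (# frames with min over ligand atoms i, residue atoms j of
> ‖a_i − b_j‖ ≤ 4 Å) / (# frames),

computed after discarding every frame up to the *last* contact with the
bottleneck residues L74/L122 (the ligand is still bound while it sits in
that bottleneck). One value per residue of a fixed reference universe;
homolog trajectories are re-indexed onto that universe through a BLOSUM62
global alignment (gap open 10, extend 0.5) with zero-fill (reference-only
residues) and drop (target-only residues) rules.

**Models.** Binary (primary tunnels T1/T2/T7 vs the rest): adaptive
boosting, 500 stumps, learning rate 0.05. Multiclass (T1-T9): random
forest, 500 trees, depth ≤ 30, 90% bootstrap fraction. Training sets are
balanced by random oversampling (after splitting, never before); splits
are stratified 70:15:15 (binary) or 70:30 with 5-fold CV tuning
(multiclass). Everything is deterministic given a seed (default 1).

**Metrics.** With confusion-matrix counts (s samples, c correct, t_k true
and p_k predicted occurrences of class k):

> BA = (1/K′) Σ_k TP_k/(TP_k+FN_k)  over the K′ classes present in the truth
>
> MCC = (c·s − Σ_k t_k p_k) / √((s² − Σ_k p_k²)(s² − Σ_k t_k²)),  0 when the denominator is 0

plus ROC/AUC for binary tasks (trapezoidal; equals the Mann-Whitney pair
statistic). A dominant-class dummy baseline anchors every comparison:
BA = 0.50 / MCC = 0.00 on a two-class test, BA = 1/9 ≈ 0.11 / MCC = 0.00 on
a nine-class test.

## Worked example

```r
library(ligandpath)

sys <- build_toy_system(n_tunnels = 9, residues_per_tunnel = 5, seed = 1)
ds  <- generate_dataset(sys, 300, config = walker_config(seed = 1))
dplyr::count(ds, label)
#>   label     n        # strong primary-tunnel imbalance, e.g. T1 109 ... T9 8

sp  <- split_multiclass(ds, seed = 1)        # stratified 70:30
fit <- train_model(sp$train, "multiclass", seed = 1)
evaluate_model(fit, sp$test)
#> <evaluation_report> multiclass task, n = 90, BA = 0.755, MCC = 0.843

evaluate_model(baseline_model(sp$train), sp$test)
#> <evaluation_report> multiclass task, n = 90, BA = 0.111, MCC = 0.000

head(tidy(fit), 3)                            # which contacts matter
#>   residue importance
#> 1 S401        0.0427
#> 2 S302        0.0351
#> 3 S803        0.0340
```

The trained model beats the 1/9 baseline by a wide margin even though the
default generator lets the ligand roam between tunnels 5% of the time;
with `roam_probability = 0` the contact signatures are fully separable and
held-out BA reaches 1.0. `autoplot(report)` draws the confusion heat map,
`autoplot(roc_curve(...))` the ROC curve, and `embed_2d()` +
`plot_embedding()` give a t-SNE QC view of any feature table.

A command-line front end wrapping the same functions lives at
`inst/cli/ligandpath.R` (subcommands `simulate`, `featurize`, `map`,
`train`, `predict`, `evaluate`).

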