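# gnnsurv

Discrete-time survival prediction on patient similarity networks, in R.

Cancer cohorts carry prognostic signal both in per-patient covariates
(gene expression, age, TNM stage) and in the *relationships* between
patients: people with similar molecular and clinical profiles tend to
share prognosis. `gnnsurv` turns a cohort into a graph — nodes are
patients, edges connect similar ones — and trains graph neural networks
on it under likelihoods that respect right censoring. It is aimed at
researchers in survival analysis and computational oncology who want a
self-contained, inspectable implementation of this modelling family.

## The method

**Graph construction.** Patient feature vectors (standardized expression
+ binary clinical covariates) are compared by correlation distance
ρ(xᵢ, xⱼ) = 1 − r(xᵢ, xⱼ). Similarity uses a locally scaled
Gaussian-density kernel

    W(i,j) = 1/√(2πσᵢⱼ²) · exp(−ρᵢⱼ² / 2σᵢⱼ²),
    σᵢⱼ = μ · (ρ̄ᵢ + ρ̄ⱼ + ρᵢⱼ) / 3

with ρ̄ᵢ the mean distance from i to its k = 20 nearest neighbours and
μ ∈ (0, 1] a bandwidth scaling selected on validation data. An edge
joins i and j when W(i,j) > c (c = 0.5, strict).

**Networks.** GCN, GraphSAGE and single-head GAT layers (plus a
graph-free MLP ablation), three blocks of layer → batch-norm → ReLU →
dropout(0.7), hidden width 32, trained full-graph with Adam (lr 1e-3,
≤ 500 epochs, early stopping on validation loss, patience 10). All
forward and backward passes are explicit dense matrix algebra — there is
no autodiff dependency — and every gradient is checked against finite
differences in the tests.

**Survival heads.** Follow-up is discretized onto an m-interval grid
(equidistant or Kaplan–Meier-quantile). Two likelihoods: *Logistic
Hazard* (per-interval sigmoid hazards; survival is the product of
1 − h) and *PMF* (softmax over intervals; censored records contribute
tail mass).

**Evaluation.** Time-dependent concordance (Antolini) and the
IPCW-weighted (integrated) Brier score over 100 equidistant times, both
censoring-aware; Kaplan–Meier estimation of the censoring distribution;
piecewise-constant-density or -hazard interpolation of discrete curves.

**Protocol.** Repeated random 64/16/20 train/validation/test splits;
the graph is cut into three disjoint subgraphs (inductive evaluation —
no message passing ever touches a held-out node); standardization and
the time grid are fitted on training data only; μ is selected per model
by mean validation concordance.

A synthetic cohort generator (`simulate_cohort()`) produces
cluster-structured expression with latent co-expression programs,
cluster-dependent discrete-hazard survival and calibrated independent
censoring, so the entire pipeline runs without any external download.

## Worked example

```r
library(gnnsurv)

co <- simulate_cohort(cohort_spec(n_patients = 200, n_genes = 100, seed = 7))
co
#> <synthetic_cohort> 200 patients, 2 clusters, censoring 56.5%

Xs <- standardize_features(co$X)
g  <- build_patient_graph(Xs, kernel_params(mu = 0.5, k_neighbors = 20))
g
#> <similarity_graph> 200 patients, 204 edges

cfg <- experiment_config(repetitions = 5, layer_types = c("gcn", "mlp"),
                         survival_models = "logistic_hazard", seed = 1)
res <- run_experiment(co$X, co$records, cfg)
aggregate_results(res)
#>   layer_type  survival_model  mu ctd_mean ctd_sd ibs_mean ibs_sd n_splits
#> 1        gcn logistic_hazard 0.5    0.706 0.0398    0.180 0.0644        5
#> 2        mlp logistic_hazard 0.5    0.723 0.0546    0.184 0.0683        5

oracle_ctd(co)
#> [1] 0.760
```

Reading the numbers: a mean test concordance of ~0.71 means that for
about 71% of comparable patient pairs the model ranks the earlier
failure as higher risk at the relevant time; the generative upper bound
on this cohort is 0.76, and a signal-free model would sit at 0.5. The
integrated Brier score (~0.18; lower is better, 0.25 is the score of a
constant 0.5 prediction) additionally measures calibration. At a single
arbitrary μ and five splits the GCN/MLP ordering is within noise —
model comparisons should use `sweep_mu()` plus validation-based
`select_mu()`, which is exactly what the acceptance script does.

A thin command-line front-end over the same functions ships in
`inst/cli/gnnsurv.R` (`simulate`, `build-graph`, `train`, `sweep-mu`,
`evaluate`).

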