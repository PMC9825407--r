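# cytoresponse

Early chemotherapy-response single-cell signaling analysis for mass
cytometry (CyTOF) cohorts.

In AML, the phospho-signaling state of the immature myeloid compartment a
few hours after the start of induction chemotherapy predicts overall
survival: patients whose blast-compartment p-ERK1/2 stays high at 24 h do
worse than patients in whom it collapses. `cytoresponse` implements the
computational chain needed to extract and validate that kind of signal
from multiplexed CyTOF acquisitions:

- **Anchored quantile normalization** — per-batch piecewise-linear maps
  between the 101 empirical quantiles (0%, 1%, …, 100%) of each batch's
  shared reference aliquot and a target batch's, applied after the
  arcsinh(x/5) transform;
- **SOM + consensus metaclustering** — a 5×5 self-organizing map trained
  on pooled pre-treatment + healthy cells over 19 surface markers,
  consensus-metaclustered into k = 10 populations; post-treatment cells are
  assigned to the nearest trained node;
- **Percentile signaling features** — per metacluster × functional marker
  × timepoint 90th-percentile intensities, 24h/0h ratios, metacluster
  sizes, age and sex (612 features in the default design);
- **Nested leave-one-out LASSO-Cox** — L1-penalized Breslow partial
  likelihood over a shared λ grid; an inner leave-one-out loop picks the
  penalty by cross-validated partial-likelihood deviance
  (Verweij–van Houwelingen) inside an outer leave-one-out loop that
  records per-fold feature selections; log-HRs per feature s.d. from an
  unpenalized refit;
- **Median-split survival analysis** — Kaplan–Meier curves, Mantel–Cox
  log-rank with the (O1/E1)/(O2/E2) hazard ratio, permutation p-values,
  time-dependent-transplant Cox confounder models, Fisher exact tests;
- **Manual blast gating** (CD45-low/CD66b-low) and **drug-sensitivity
  scoring** (plate control normalization, isotonic DSS, selective DSS
  against healthy donors, top-target tallies);
- a **synthetic cohort generator** with full ground truth (cell population
  labels, batch distortion parameters, per-patient treatment response,
  survival mechanism) so the entire pipeline is testable end to end with
  no external data.

The model at the core: for standardized latent 24 h response `z`, survival
follows a proportional-hazards law `h(t) = h0 · exp(β·z)`; the pipeline's
job is to recover the feature carrying `z` from ~600 candidates measured
on a few dozen patients, and the generator makes `β` and the causal
feature known so recovery is checkable.

## Worked example

```r
library(cytoresponse)

spec <- cohort_spec(n_patients = 32, n_batches = 7,
                    cells_per_sample = 1000, seed = 2)
run <- run_pipeline(spec, seed = 2)
run
#> <cytoresponse_run> 32 patients, 612 features, horizon 5y
#>   split feature: MC8_pERK_ratio24h (groups 16/16)
#>   log-rank p = 5.301e-06, HR low/high = 0.07555 (95% CI 0.02697-0.2117)
#>   selected features:
#>             feature log_hr        p    p_adj p_univariate selection_frequency
#> 1 MC8_pERK_ratio24h   1.51 0.000122 0.000122     0.000122               0.906
```

Reading the output: the nested LOOCV selected the 24h/0h ratio of the
90th-percentile p-ERK signal in metacluster 8 — on this synthetic cohort,
the metacluster holding the generator's target myeloid population
(`target_metacluster(run)` confirms it) — with a log hazard ratio of 1.51
per standard deviation and a leave-one-out selection frequency of 0.91.
Splitting the 32 patients at the median of that feature gives 16/16 groups
whose 5-year survival differs by log-rank p ≈ 5e-6; the low group's hazard
is ~0.08× the high group's, i.e. sustained 24 h signaling marks the
poor-prognosis arm, which is exactly the mechanism the generator encodes.
At this cohort size the parsimony rule leaves some seeds' final models
empty; the run report then falls back to the top selection-frequency
feature for the median split.

Individual stages are exposed as plain functions (`arcsinh_transform()`,
`fit_quantile_maps()` / `apply_quantile_maps()`, `train_som()` /
`metacluster()` / `assign_cells()` / `subcluster()`,
`extract_sample_features()` / `build_feature_matrix()`,
`nested_loocv_select()`, `median_split()`, `km_estimate()`,
`logrank_test()`, `fit_cox_td()`, `fisher_exact()`, gating and DSS
functions). A thin command-line wrapper lives in
`inst/scripts/cytoresponse-cli.R`. The methods vignette
(`vignettes/early-response-pipeline.Rmd`) documents the model, parameter
choices, numerical conventions and limitations.

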