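# zsustain

Subtype and stage inference for regional brain atrophy from
cross-sectional morphometry.

Temporal lobe epilepsy — like several other brain disorders — appears to
comprise distinct *biotypes*: subgroups whose gray-matter atrophy starts
in different places and spreads along different routes, and which respond
differently to surgery and medication. With one MRI scan per patient,
progression cannot be observed directly; it has to be inferred from where
along its own course each cross-sectional scan happens to sit. `zsustain`
is an R implementation of that inference chain for regional morphometry
tables, aimed at imaging researchers who have FreeSurfer-style per-region
measures plus clinical covariates.

## What it does

1. **Normative z-scoring** (`fit_normative`, `compute_zscores`): per-ROI
   least squares on healthy controls (sex, age, age², TIV), then
   atrophy-positive deviations `z = -(y - ŷ)/σ̂` so that larger z means
   more tissue loss.
2. **z-score event-based subtype and stage inference** (`fit_subtypes`,
   `select_model_order`, `assign_individuals`): events are (ROI,
   threshold) pairs with waypoints z = 1, 2, 3; a trajectory is an event
   ordering; a subject at stage k is modelled as
   `x_b ~ N(g_b(k), σ_b)` with `g` the piecewise-linear expected
   trajectory, the stage marginalized under a uniform prior, and subjects
   mixed over C trajectories. Fitting is greedy multi-start ascent with
   hierarchical cluster splitting and hard EM; ordering uncertainty comes
   from Metropolis MCMC (`mcmc_sample`, `positional_variance`); the number
   of trajectories is chosen by the cross-validation information criterion
   (CVIC, lower is better). Subjects with all modelled z < 1 get the
   rule-based label `"normal"` at stage 0.
3. **Subtype characterization** (`stage_atrophy_correlation`,
   `roiwise_group_comparison`, `clinical_compare`,
   `seizure_freedom_table`): Spearman stage-atrophy correlations, ROI-wise
   t contrasts with Benjamini–Hochberg FDR, ANOVA + LSD and Pearson
   chi-square clinical comparisons, and seizure-freedom rates with
   one-vs-rest chi-squares (uncorrected, loss-excluded denominators).
4. **Surgical-prognosis classification** (`build_features`,
   `evaluate_stratified`, `evaluate_pooled`, `permutation_test`,
   `youden`): one SVM sub-classifier per subtype under 10-fold CV with
   per-fold standardization and PCA, Youden-index summary, and a
   label-permutation null.
5. **Synthetic cohorts with ground truth** (`make_ground_truth`,
   `simulate_cohort`, `simulate_outcomes`): 76 ROIs, three planted
   trajectories (left-hippocampus-first, right-hippocampus-first,
   frontal-cortex-first), a no-atrophy subtype with amygdala enlargement,
   and subtype-dependent treatment outcomes — used throughout the tests
   for parameter recovery.

`run_pipeline()` drives the whole chain from a declarative (YAML or list)
config and writes CSV/JSON artifacts per stage.

## Worked example

Simulate a study-sized cohort, z-score it against its own controls, fit
three trajectories and inspect the result:

```r
library(zsustain)

gt     <- make_ground_truth(seed = 1)
cohort <- simulate_cohort(gt, n_patients = 296, n_controls = 81, seed = 2)

controls <- subset(cohort$morphometry, group == "control")
patients <- subset(cohort$morphometry, group == "patient")

nm <- fit_normative(controls)
Z  <- select_modeling_rois(compute_zscores(nm, patients),
                           default_modeling_rois())

model  <- fit_subtypes(Z, gt$event_set, k = 3,
                       control = sustain_control(n_starts = 5,
                                                 mcmc_iter = 1e4),
                       seed = 3)
assign <- assign_individuals(model, Z)

table(assign$label)
#>       normal trajectory_1 trajectory_2 trajectory_3
#>           30          140           74           52

stage_atrophy_correlation(assign, Z)
#>          label   n       rho             p
#> 1 trajectory_1 140 0.9897791 1.282241e-118
#> 2 trajectory_2  74 0.9923479  3.699683e-67
#> 3 trajectory_3  52 0.9908161  4.032427e-45
```

This seed generated 83/106/44 trajectory subjects and 63 no-atrophy
subjects. With labels matched by best permutation (subtype indices are
arbitrary), 89.7% of trajectory-subtype subjects recover their generating
trajectory, and within every trajectory the assigned stage correlates
strongly with the mean modelled z-score — the stage axis tracks atrophy
burden, which is what makes it interpretable as a progression coordinate.
Only 30 of the 63 no-atrophy subjects land under the stage-0 rule here:
the rule thresholds *estimated* z-scores, and with 81 controls the
estimation noise pushes borderline subjects over z = 1 (on the generator's
true z-scores the rule is exact; see the tests).

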