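---
title: "Subtype and stage inference for regional brain atrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype and stage inference for regional brain atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zsustain)
```

## The problem

Temporal lobe epilepsy (TLE) presents with a fairly homogeneous clinical
picture, yet 40–50% of patients fail to achieve long-term seizure freedom
after anterior temporal lobectomy. One hypothesis is that the clinical
label hides several *biotypes* with distinct spatiotemporal patterns of
gray-matter atrophy, and that those biotypes differ in surgical and
pharmacological prognosis. Longitudinal imaging across the disease span is
rarely available, so the progression pattern has to be inferred from
cross-sectional data: many patients, one scan each, at unknown points
along their own disease course.

`zsustain` implements the full analysis chain for this setting:

1. **Normative z-scoring** of regional morphometry against a
   healthy-control regression model,
2. a **z-score event-based subtype-and-stage model** (the SuStaIn family
   of models) that infers a small number of event *orderings*
   ("trajectories") plus a per-subject *stage*,
3. **characterization statistics** for the resulting subtypes, and
4. a **subtype-stratified SVM classifier** of surgical outcome.

A synthetic cohort generator with known ground truth stands in for
protected patient data and lets every inferential step be validated by
parameter recovery.

## Normative model

For each region of interest (ROI) the raw measure $y$ (volume in mm³ for
subcortical structures, thickness in mm for cortical parcels) is regressed
on sex, age, age², and total intracranial volume (TIV, cm³) **in healthy
controls only**:

$$y = \beta_0 + \beta_1\,\mathrm{sex} + \beta_2\,\tilde a +
      \beta_3\,\tilde a^2 + \beta_4\,\mathrm{TIV} + \varepsilon,\qquad
      \tilde a = \mathrm{age} - \overline{\mathrm{age}}_{\mathrm{ctrl}}.$$

Controls-only estimation is the normative convention: it prevents patient
atrophy from leaking into the reference surface. Age is centered before
squaring to keep the linear and quadratic terms from being nearly
collinear (configurable off). The per-ROI *residual* standard deviation
$\hat\sigma$ (denominator $n-5$) — not the raw control SD — is the
normative scale, so that

$$z = -\,\frac{y - \hat y}{\hat\sigma}$$

is a covariate-adjusted normative deviation. The sign flip makes z
*atrophy-positive*: z grows as tissue is lost, and regional enlargement
(as in the amygdala of the no-atrophy subtype) appears as negative z.
ROIs whose residual SD falls below $10^{-8}$ are refused as degenerate.

## The progression model

An **event** is a pair (biomarker, z-threshold). The default thresholds
are the waypoints $z = 1, 2, 3$ for every modelled ROI; with $B$
biomarkers this gives $E = 3B$ events and an integer stage axis
$0 \dots E$. A **trajectory** is a permutation $S$ of all events in which
each biomarker's thresholds appear in increasing order. The expected
z-score of biomarker $b$ at stage $k$, $g_b(k)$, is the piecewise-linear
interpolant through $(0,0)$, the biomarker's event positions and
thresholds, and $(E, z_{\max})$; if the biomarker's last event occupies
position $E$ its threshold anchor takes precedence. $z_{\max} = 5$ by
default — the plateau reached after the last threshold — and the
per-biomarker noise SD defaults to $\sigma_b = 1$ because the inputs are
normative z-scores. Neither constant is dictated by the data model, so
both are exposed as configuration.

A subject's likelihood marginalizes the unknown stage under a uniform
prior:

$$L(x \mid S) = \frac{1}{E+1}\sum_{k=0}^{E}\ \prod_{b=1}^{B}
  \mathcal N\!\left(x_b;\, g_b(k),\, \sigma_b\right),$$

and $C$ subtypes form a mixture $\sum_c f_c\, L(x \mid S_c)$ with
fractions $f_c$. Log-sum-exp stabilisation is used throughout.

## Fitting

* **Greedy ascent.** From each of `n_starts` random valid orderings
  (default 25), passes over the events relocate each event to its best
  valid position until no relocation improves the likelihood.
* **Hierarchical splitting.** The $k$-subtype solution grows from the
  $(k-1)$-solution: each cluster is candidate-split by random bipartition,
  each half refitted by greedy ascent, and the candidate refined by hard
  EM over *all* subjects (hard reassignment, per-cluster warm-started
  partial ascent, fraction update). The split with the highest total
  mixture likelihood wins; fractions are the converged assignment
  proportions. A cluster that empties under hard assignment keeps a
  half-subject floor on its fraction rather than invalidating the
  candidate — this is what lets the model order be scanned past the true
  number of subtypes.
* **MCMC.** Ordering uncertainty comes from a Metropolis sampler: one
  subtype and one event chosen uniformly, the event relocated to a
  uniformly chosen *valid* position (the window of valid slots has the
  same size before and after a move, so the proposal is symmetric), the
  move accepted with probability $\min(1, e^{\Delta\log L})$. Fractions
  stay fixed, keeping the chain a pure ordering sampler. Every 10th state
  is stored; the reported orderings are the maximum-likelihood states over
  the chain, and the positional variance diagram (fraction of samples
  placing event $e$ at position $p$) summarizes uncertainty.
* **Model order.** CVIC: subjects are split into folds without
  stratification, the hierarchy is fitted on the training folds, and the
  held-out log-likelihood is averaged over the training fit's MCMC
  samples. $\mathrm{CVIC}(k) = -2\sum_{\text{folds}}\ell_{\text{test}}$;
  the smallest CVIC wins.
* **Assignment.** Each subject gets the mixture posterior over subtypes,
  the MAP trajectory, and the MAP stage within that trajectory restricted
  to $1..E$. Subjects whose modelled z-scores are *all* below 1 are
  labelled `"normal"` with stage 0 — the rule-based fourth subtype.
  Restricting staged subjects to stages $\geq 1$ keeps the two halves of
  the rule consistent (stage 0 if and only if the label is `"normal"`).
  The model is fitted on all subjects and the rule applied post hoc.

## What the generator emulates — and what it does not

`make_ground_truth()` + `simulate_cohort()` emit the same CSV schemas the
readers accept: 76 ROIs (12 subcortical volumes, 64 cortical thickness
parcels), of which 23 form the default modelling subset (bilateral
hippocampus and thalamus plus 19 cortical regions; the amygdala is
deliberately excluded so its enlargement stays visible to characterization
without entering the trajectory model). Defaults mirror the study
conditions: 296 patients and 81 controls; subtype fractions
28.7 / 38.2 / 13.9 / 19.2%; three trajectories whose first events are the
left hippocampus, the right hippocampus, and a frontal cortical region at
$z = 1$, with the remaining order randomized per seed; control covariates
age $\sim\mathcal N(26.4, 6.7)$ years truncated to [18, 60], balanced sex,
TIV $\sim\mathcal N(1470, 140)$ cm³. Trajectory subjects draw a stage
uniformly on $1..E$ (the model's own prior; no stage distribution is
specified by the study design) and modelled z-scores
$\mathcal N(g_b(\text{stage}), 1)$; "normal" subjects draw all modelled z
below 1 and amygdala z $\sim\mathcal N(-1.5, 0.8)$ (an enlargement
magnitude chosen as a plausible stand-in — only its significance, not its
size in z units, is constrained by published results). Planted z-scores
are mapped back to the raw measurement scale by inverting the covariate
model, so the pipeline's regression step is genuinely exercised rather
than bypassed. Clinical columns (onset age, duration, lateralization,
hippocampal-sclerosis flag, febrile history, aura, treatment arm) and
per-(subtype, arm) seizure-freedom and loss-to-follow-up probabilities
follow the published subtype-level moments.

Limitations to keep in mind when reading passing tests: onset age and
illness duration are drawn independently of the subject's age (their sum
is not constrained); covariate effect sizes are plausible defaults, not
estimates; there is no scanner/site structure, no spatial correlation
between neighbouring ROIs, and no label noise in the clinical columns.
Recovery results on this generator therefore demonstrate correctness of
the inference machinery under the model's own assumptions, not performance
on real MRI.

## Prognosis classifier

Operated subjects with known follow-up are featurized (one-hot categorical
encoding, optional MRI z-score block). Under 10-fold cross-validation each
subtype gets its own support-vector sub-classifier; standardization and
PCA (components up to 95% cumulative variance) are refitted on training
rows only, so no information leaks from test folds. The kernel is chosen
per stratum by inner 5-fold cross-validation among linear, RBF and
polynomial (configurable to a fixed kernel); training is unweighted by
default, with inverse-frequency class weights available. The summary is
the Youden index $J = \text{sensitivity} + \text{specificity} - 1$, and
significance comes from permuting outcome labels and repeating the entire
cross-validation ($p = (1 + \#\{J_\pi \ge J\})/(1 + n_\pi)$, default
$n_\pi = 1000$; fewer than 100 permutations is refused as unstable). A
pooled single-classifier baseline reuses the same folds for a paired
comparison. Strata whose training folds contain one outcome class are
skipped with a warning and excluded from pooled metrics.

## Numerical choices

* Stage axis is integer; no fractional stages.
* Greedy improvement tolerance $10^{-9}$; ascent passes capped at 200.
* Random valid orderings: a uniform permutation whose within-biomarker
  slots are re-filled in threshold order.
* Hard-EM candidates iterate at most 10 times with a 3-pass partial
  ascent per refit (generalized EM — the classification log-likelihood is
  non-decreasing either way).
* Label matching across independent fits uses maximum-agreement
  permutation matching; `"normal"` is rule-defined and matched to itself.
* Chi-square tests are Pearson without continuity correction; FDR control
  is Benjamini–Hochberg; post-hoc LSD t-tests share the pooled ANOVA
  error term; seizure-freedom denominators exclude subjects lost to
  follow-up.

## Problem sizes used by the shipped tests

The published setting uses 25 greedy starts and $10^6$ MCMC iterations.
The package defaults are 25 starts and $10^5$ iterations; the test-suite
and validation runs use a reduced profile (3–5 starts, 2–3 bipartitions
per split, $10^4$ iterations, 3-fold CVIC over $k = 2..4$) at the full
cohort size of 296 patients and 23 modelled ROIs. At this profile the
full-scale recovery checks (CVIC selecting three trajectories, ≥85%
trajectory-label recovery, ordering Kendall τ ≥ 0.8) run in minutes;
results at this scale are property-checked, not value-matched, since the
cohort-bound published numbers depend on protected data.
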