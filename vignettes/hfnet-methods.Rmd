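---
title: "Methods: network features and stacked ensembles for HF risk in IHD patients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network features and stacked ensembles for HF risk in IHD patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfnet)
```

## The problem and the modelling idea

Administrative hospital-discharge data record, for every inpatient stay,
a set of ICD-10 diagnosis codes plus basic demographics. `hfnet` asks
whether the *sequence of comorbidity sets* across a patient's admissions
predicts progression from ischemic heart disease (IHD, I20–I25) to heart
failure (HF, I50), without any clinical measurements.

The central assumption is that the case and control populations differ in
their comorbidity *structure* — which diseases appear, how often, and in
what order — and that this structure can be summarised as a weighted
directed graph and compared patient-by-patient against a cohort-level
reference graph. All modelling operates on ICD-10 three-character
categories: finer codes are truncated (`truncate_icd()`), which trades
specificity for statistical support per node.

## Cohort construction

`assign_cohorts()` applies three rules in order: patients with no IHD code
are excluded; patients whose first HF admission does not come strictly
after their first IHD admission are excluded (this covers both HF-first
and same-admission co-diagnosis, where the temporal direction IHD→HF is
unidentifiable); patients with fewer than three total admissions are
excluded (too little trajectory to model). Survivors are cases if HF ever
occurs, controls otherwise.

Case histories are then **censored** at the first HF admission
(`censor_case_history()`): features are computed from strictly pre-HF
admissions. A risk model scored on admissions that already contain the
outcome code would be answering a different (and trivial) question; the
HF admission itself, and everything after it, is therefore invisible to
the features. The uncensored variant remains available
(`censor = FALSE` in `extract_network_features()`) for sensitivity
analyses. Indices reported by `assign_cohorts()` are the input's own
`admission_index` values.

## The three networks

- **PDN** (per patient): node weight = number of admissions containing
  the disease; edge weight = co-occurrence counts in the same or
  consecutive admissions. Same-admission pairs have no temporal order, so
  they contribute 1 to *both* directed edges; consecutive-admission pairs
  contribute 1 to the forward edge only. Self-loops are excluded: a
  disease recurring across admissions is already captured by its node
  weight, and a self-edge would let chronically recoded diagnoses swamp
  the edge vector.
- **BDN** (per cohort): elementwise sum of the cohort's PDNs, then
  divided by the number of patients (`to_relative_frequency()`) so the
  two cohorts are comparable despite their different sizes.
- **DSN**: for every node and edge, `max(0, case_rf − control_rf)`
  (`difference_clamped`, the default). The clamp is the simplest monotone
  implementation of "weight what is more prevalent on the IHD→HF
  trajectory, discount the opposite": conditions more typical of controls
  drop out entirely rather than entering with negative weight. A signed
  variant (`difference_signed`) is provided for comparison. Nodes whose
  weight is clamped away but which still anchor a surviving edge are kept
  at a floor of `epsilon = 1e-9` so the edge set remains well-formed;
  the floor is far below any real relative frequency and contributes
  ~1e-18 to squared norms, i.e. nothing.

Networks are built from a **65% partition** of the included patients
(stratified by cohort, `split_network_vs_modeling()`); the remaining 35%
are scored against the *frozen* DSN and used for model training and
evaluation. Re-using network patients for modelling would leak cohort
labels into the features through the DSN itself.

## Features

For a patient's PDN and the frozen DSN:

- `node_score` and `edge_score` are cosine similarities of the weighted
  disease / directed-edge vectors. The dot product runs over shared
  entries; the norms run over each network's *full* vector, so a patient
  with many diseases outside the DSN is penalised. Degenerate cases
  (empty vectors, empty intersection) score 0 — "maximally dissimilar" —
  rather than NaN, keeping the feature table complete.
- `rank_score` weights the patient's disease frequencies by the DSN
  PageRank importance of shared diseases and divides by the total number
  of distinct PDN diseases (shared or not — the literal reading of the
  denominator). PageRank (damping 0.85, uniform teleport, dangling nodes
  redistributing uniformly, power iteration to an L1 tolerance of 1e-10,
  at most 1000 sweeps) is computed once on the DSN. Scores are passed to
  the models unscaled: their magnitude depends on DSN size, but the tree
  learners are scale-free and the linear baselines standardise all
  inputs anyway.

Cosine scores are invariant to any positive rescaling of DSN weights, and
PageRank is normalisation-invariant, so the features do not depend on the
overall scale of the specificity weights — only on their shape.

## The DXLR ensemble

Stage 1 fits three base learners — a CART decision tree, depth-wise
gradient-boosted trees, and leaf-wise (best-first) gradient-boosted trees,
the growth strategy popularised by LightGBM — and produces for every
training row an out-of-fold probability from a stratified 5-fold split
(identical folds for all learners). Stage 2 appends the "crucial
features" — each base learner's single most important input feature by
impurity/gain importance from a refit on the full training partition,
deduplicated, ties broken by the fixed feature order — and fits a
random-forest meta learner (300 trees) on the combined matrix. New data
are scored by averaging each learner's five fold models into
meta-features and feeding them, plus the crucial columns, to the meta
learner.

Class imbalance (roughly 1:2 cases:controls) is handled with SMOTE
(k = 5 minority neighbours, uniform interpolation, resampling to 1:1)
applied **inside training folds only** — never to validation folds or
test data, which would manufacture synthetic rows into the evaluation.

Hyperparameters are selected by grid search under stratified 10-fold
cross-validation maximising AUC. The shipped grids contain a single,
fixed parameter set per learner (tree depth 4–6, 120 boosting rounds at
learning rate 0.1, 15 leaves for the leaf-wise learner, cost 1 for the
SVM): at the few-hundred-row table sizes this package targets, wider
grids mostly reward noise, and fixed mid-range values keep the repeated
protocol fast and exactly reproducible. The search machinery is fully
functional — supply a longer `grid` to any learner constructor to enable
it.

The linear baselines (logistic regression, linear-kernel SVM) standardise
inputs with training-set parameters; the SVM emits Platt-calibrated
probabilities. The classification threshold for the threshold metrics is
0.5 unless configured.

## Evaluation protocol

`repeated_split_evaluation()` repeats: stratified 80/20 split → tuning and
fitting on the 80% (SMOTE inside) → metrics on the untouched 20%; results
are mean ± SD over repeats, with per-repeat seeds derived from one master
seed. AUC is the exact Mann–Whitney rank statistic with ties counted ½.
Precision with no positive predictions is reported as 0 with a warning;
AUC on a single-class subgroup is skipped for that repeat and the skip
counted (`subgroup_analysis()`). Subgroup analysis stratifies only the
*test-set evaluation* (sex; ages 18–44, 45–59, 60–69, 70–79, 80+); models
are always trained on the full training data. Sex contrasts use a
two-sample t-test over per-repeat metrics, age contrasts a one-way ANOVA;
these are descriptive companions, not gatekeepers.

Feature attributions are exact interventional Shapley values computed by
coalition enumeration against a finite background sample — feasible
because the model sees at most a handful of features — first over the
meta learner's inputs, then propagated to the five input features: each
out-of-fold column's attribution is distributed across the inputs in
proportion to that base learner's own absolute attributions, and
crucial-feature columns map to themselves. This preserves additivity
exactly: per row, signed attributions sum to prediction − base value.

## The synthetic generator

Real discharge databases are access-restricted, so the package generates
cohorts with the statistical structure the method assumes. Every patient
receives an IHD code on the first admission; cases receive I50 on one
extra terminal admission appended after a core trajectory drawn from the
same length distribution as controls (1 + Poisson(4), minimum 1), which
keeps censored case histories and control histories nearly exchangeable
under the null. Codes appear on an admission independently with
configured probabilities (≈3 expected diagnoses per admission for
controls, ≈5 for shifted cases; at least one enforced), so empirical
per-admission prevalences converge to the configured values — the
property the generator's tests verify. A separate per-admission count
distribution is deliberately *not* exposed: it is implied by the
prevalence vector.

Signal is planted through two independent channels so each feature
family can be probed separately:

- **prevalence shifts** (default +0.4 on atrial fibrillation I48, CKD
  N18, COPD J44, type 2 diabetes E11, hypertensive heart disease I11) —
  drives node and rank scores;
- **transition motifs** (default E11→N18, I10→I11, I48→I63, each +0.3
  extra probability in the following admission of cases) — drives the
  edge score, with a weaker induced marginal shift on the target codes.

Ages follow the group-specific normals (cases 74.3 ± 9.6, controls
68.3 ± 10.7, truncated to 18–100); sex is Bernoulli(0.48 male). Shifted
probabilities are clipped to [0, 1] with a warning, never renormalised —
renormalising would silently change every other code's prevalence.
`generate_null_population()` zeroes both signal channels *and* draws both
groups' ages from the control distribution: age is a model feature, so a
residual age gap would itself be signal, and the null population must
carry none beyond the structural marker codes.

What the generator does **not** emulate: ICD-10 hierarchy below
three-character categories, calendar time and inter-admission gaps,
length of stay, mortality/competing risks, coding-practice drift across
hospitals, and correlated comorbidity clusters beyond the planted
motifs. Passing tests therefore demonstrate that the pipeline recovers
the kinds of structure it is designed for — not that it would achieve
any particular performance on real discharge data.

## Study sizes and experiment design

The shipped experiments use sizes chosen to make their conclusions
statistically meaningful at desk scale:

- *Signal recovery and null control*: 500 cases / 1,000 controls
  (matching the roughly 1:2 real-world cohort imbalance), 10 repeats of
  80/20 on the ~490-row modeling partition.
- *Ablation direction*: 1,000 / 2,000 patients and 30 repeats, giving a
  standard error on mean AUC of about 0.007 — ablation deltas are of
  order 0.01–0.04 and would drown at smaller sizes. The ablation
  configurations plant signal through a single channel, equalise ages
  across groups (so network features are the only carriers), and use a
  moderate prevalence shift of +0.15: at the headline +0.4 the
  classifiers sit at the AUC ceiling, where removing a feature costs
  nothing and ablation orderings are meaningless.

A note on what ablation can show: `node_score` and `rank_score` are both
functionals of the same PDN∩DSN node overlap and are nearly redundant —
removing either one alone barely moves the AUC as long as the other
remains. The informative contrasts are removing the *pair* versus
removing `edge_score` (under marginal-prevalence signal), and removing
`edge_score` versus either node functional (under transition-motif
signal). The edge score also carries secondary marginal signal, because
more prevalent diseases co-occur more; the channels are separable, not
orthogonal.

## Numerical choices and degenerate inputs

- Cosine and rank scores return 0 (not NaN) on empty supports.
- DSN ε-floor 1e-9 for orphaned edge endpoints; clamped-to-zero entries
  are removed outright.
- PageRank: tolerance 1e-10, max 1000 iterations, final renormalisation
  to kill float drift; scores sum to 1 within 1e-9.
- Crucial-feature ties resolve by the fixed input-feature order, making
  selection deterministic.
- SMOTE with a single minority row replicates it; with fewer than k
  neighbours, k shrinks.
- Stratified folds require every class to have at least one row per
  fold; violations are errors, not silent merges.
- All stochastic steps (generation, splits, folds, SMOTE, forests) run
  under explicit integer seeds; identical seeds give byte-identical
  results.

## Known limitations

- The DSN uses no statistical significance filtering of edges (relative
  risk, φ-correlation); rare-code noise is only damped by the
  relative-frequency difference and the clamp.
- Features compare each patient to a single cohort-level reference
  graph; patient-to-patient similarity is out of scope.
- The evaluation protocol re-tunes and re-fits per repeat, which is
  honest but quadratic in repeats × grid size; the shipped single-point
  grids keep this tractable.
- Synthetic validation bounds what can be claimed about real data (see
  the generator section above).
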