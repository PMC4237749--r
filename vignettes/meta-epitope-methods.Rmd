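---
title: "Meta-learning for per-residue B-cell epitope prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-learning for per-residue B-cell epitope prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistack)
```

## The problem

B-cell epitopes are the antigen surface residues recognized by antibodies.
Many per-residue epitope predictors exist — some scoring linear (sequence-
contiguous) epitopes, some conformational (structure-discontinuous) ones —
and their predictions only weakly agree: pairwise score correlations sit
around 0.3–0.5, and individual tools trade sensitivity against specificity
very differently. That weak agreement is an opportunity: learners with
complementary error profiles can be *arbitrated* by a second-level learner
that sees all of their outputs at once.

`epistack` implements that arbitration as two meta-learning hierarchies:

* **Stacked generalization** — parallel composition. Base predictor scores
  (and base features) feed one or more meta learners whose outputs become
  *meta features* for a top-level arbiter. The two-level variant trains a
  single meta learner; the three-level variant trains a decision tree, a
  k-nearest-neighbour classifier, and a feed-forward neural network in
  parallel at level 1 and an SVM on top.
* **Cascade generalization** — sequential composition. Exactly one learner
  per level; its prediction is appended to the feature block of the next
  level, so level *j* sees the base block plus *j − 1* meta-feature columns.

The package treats the external base predictors strictly as per-residue
score columns: it never re-implements them. What it does compute natively
are the sequence-propensity base features (windowed Parker hydrophilicity,
Kyte–Doolittle hydropathy, Kolaskar–Tongaonkar antigenicity, and
Karplus–Schulz flexibility profiles, plus a four-way side-chain polarity
indicator); structure-derived features (accessibility, secondary structure,
B factors, surfaces, PSSM, atom volume) require external structure software
and are ingested as precomputed columns.

## Data model

Every table is keyed by residue: `(antigen_id, chain, position, aa)`.
Feature, score, and label tables are joined on that key by
`assemble_dataset()`, which keeps the key intersection, drops residues with
any missing value (counting and reporting them — the `fail` policy errors
instead), and stores row-aligned matrices. Residue positions are author
numbering treated as opaque labels; sequence windows are computed on
1..length coordinates of each sequence independently.

## Out-of-fold meta features

Stacking and cascading both risk leakage: if a level-1 learner predicts the
very residues it was trained on, the top learner learns to trust an
optimistically accurate input. During training, every meta-feature column
is therefore built **out-of-fold**: the training set is split into
`oof_folds` (default 5) stratified folds, and each residue's meta feature
comes from a model fitted on the other folds. The fitted object's manifest
records the fold assignment and per-fold training indices, so tests audit
leakage structurally rather than by trust. At prediction time the
full-data level-1 models generate the meta features; this is standard
stacking practice.

Meta features default to predicted probabilities (`meta_feature_form =
"probability"`), which preserve the learner's confidence; hard labels are
available for strict reproduction of label-passing hierarchies.

## Learners and their settings

| learner | implementation | defaults |
|---|---|---|
| `tree` | CART (`rpart`) | `cp = 0.01`, `minsplit = 20` |
| `knn`  | `class::knn`   | `k = 3`, z-scored inputs |
| `ann`  | `nnet` (1 hidden layer) | 16 units, `decay = 0.01`, `maxit = 100`, seeded init |
| `svm`  | `e1071::svm`, RBF | `cost = 1`, `gamma = 1/ncol`, Platt probabilities |

CART stands in for C4.5: both are univariate-split decision trees with
pruning, and no C4.5 implementation is part of the supported stack.
The SVM's `cost`/`gamma` can be grid-searched (`svm_tune = TRUE` in
`learner_control`), but the default keeps them fixed: cross-validation and
greedy ablation refit the architecture dozens of times, and a nested grid
search multiplies that cost for little change in the comparisons the
package is built to make (all architectures share whatever setting is
chosen). Features are standardized (training statistics only) for the
distance- and margin-based learners; trees consume raw values.

Class imbalance (epitope prevalence ~4%) is left as-is, matching the
training regime the hierarchy is meant for; an optional
`class_weights = TRUE` flag reweights inversely to class frequency. The
classification threshold on meta probabilities is fixed at 0.5.

The stack3 wiring question — whether the top learner receives the raw base
scores alongside base features and meta features — is genuinely open in the
source architecture diagrams; both wirings are supported
(`include_base_tool_outputs_at_top`, default `TRUE`, since withholding
information from the arbiter needs a positive reason).

## Base-predictor thresholds

Each external tool's score column is binarized at a threshold tuned by
systematic grid search (`optimize_threshold()`): every candidate in an
arithmetic grid (default step 0.01, e.g. 0.01…0.99 on a unit-range score) is
evaluated and the maximizer of the chosen measure returned, ties to the
smallest threshold. The tuning measure defaults to MCC — the measure used
to arbitrate the ablation analyses — because the tuned-for quantity should
match the compared quantity; it is configurable because the original
tuning objective is not recorded.

## Evaluation

`metrics()` computes TPR, FPR, precision, accuracy, F-score, and MCC from a
confusion matrix, with fixed zero-division conventions (precision 0 when
nothing is predicted positive; F-score 0 when TPR + precision = 0; MCC 0
when any denominator factor vanishes). ROC curves sweep all distinct
observed scores and integrate by trapezoid (via pROC); AUC equals the
Mann–Whitney statistic, which the test suite asserts independently.

Cross-validation is **two stratified five-fold CVs** by default
(`cv_spec()`), grouped by antigen so no protein contributes residues to
both sides of a split. Stratification is greedy: antigens are assigned,
largest epitope count first, to the fold whose positive count stays most
balanced. The overall performance is the mean over all repeat × fold
results; `paired_ttest()` compares architectures fold-by-fold.

`reconstruct_confusion()` inverts rounded published rate triples
(TPR, FPR, precision; half-up rounding at 3 decimals) back to integer
confusion matrices by exhaustive search over (TP, FP). The inversion is
usually unique; when several integer pairs are consistent the function
refuses to guess and lists the candidates, and additional published rates
(accuracy, F-score, MCC) can be supplied to disambiguate — one published
single-tool row genuinely needs its MCC for uniqueness.

## Greedy ablation

`backward_eliminate()` starts from the full meta classifier and, per
iteration, evaluates every single-component removal, removing the component
whose removal degrades the measure most (the most influential component
leaves first) and recording the resulting model's metrics, down to the
features-only model. `forward_select()` mirrors this, adding the best
candidate per iteration, e.g. starting from the conformational-only model
and adding linear tools. Candidate ties break lexicographically; the
default measure is MCC; the default protocol is train-on-train /
measure-on-held-out, with a CV protocol available for data-scarce use.
`block_ablation()` compares the full model against tool-only and
feature-only variants under one protocol. Exhaustive all-subsets ablation
is deliberately out of scope (exponential cost).

## The synthetic generator

Real score tables require eight external web servers, so the package ships
a generator (`synthetic_config()`, `generate()`, `preset_paperlike()`)
reproducing the statistical regime those tables live in:

* **Prevalence and runs.** Epitope residues are drawn as contiguous runs
  (geometric lengths, mean 8 residues) within each antigen until
  `round(length × fraction)` positives exist, so the positive count is
  controlled to within rounding. The default fraction 0.0425 matches the
  201-in-4729 class balance of the emulated independent test regime.
* **Score model.** Learner *j* scores residue *i* as
  *s*~ij~ = *β*~j~ *y*~i~ + *λ*~j~ᵀ*z*~i~ + *e*~ij~ with a shared latent
  factor *z* (controls pairwise correlation via the loadings) and unique
  noise. *β*~j~ is solved from the binormal identity
  AUC = Φ(*β*/√(2*v*)) so every learner hits its target AUC in
  population.
* **Preset.** Eight learners (four "conformational", four "linear") with
  AUC targets 0.55–0.79 and a single factor with loadings ≈ 0.6, giving a
  mean pairwise Pearson correlation near 0.38 — the weak-correlation,
  modest-discrimination regime in which arbitration can help. Ten feature
  columns carry graded class shifts from 1.2 SD down to 0 (some features
  informative, some noise).

What the generator does **not** emulate: 3D structure, spatial
autocorrelation of scores along the chain beyond label runs, realistic
physicochemical feature marginals, or antigen-to-antigen heterogeneity in
predictor quality. Passing tests on synthetic data therefore demonstrate
that the machinery is correct and that arbitration works *when the assumed
regime holds* — not that any particular performance level transfers to real
antigens.

## Problem sizes in tests and the acceptance script

The package's experiments run at reduced scale, chosen so a full
train/evaluate cycle is seconds rather than minutes: training sets of 24
antigens × 45–60 residues (~1 300 residues) and test sets of 15 antigens ×
150–170 residues (~2 400 residues, the emulated class balance); parameter-
recovery checks use ~5 000 residues. These sizes keep Monte-Carlo noise
well inside the tolerances asserted while exercising every code path at
realistic prevalence.

## Known limitations

* C4.5's exact pruning heuristics are not reproduced (CART stands in).
* `class::knn` probabilities at k = 3 are coarse (4 levels); they are used
  as-is, which slightly quantizes knn-derived meta features.
* Mapping window-based linear-predictor outputs onto structure residues is
  the data producer's responsibility: all score tables arrive per-residue.
* The paired t test over fold results ignores the dependence between folds
  (standard practice, but p-values are approximate).
* With zero variance of paired differences the t test degenerates; the
  package warns and reports p = 1.
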