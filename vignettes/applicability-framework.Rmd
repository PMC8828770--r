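---
title: "Predicting biomarker applicability with paired outcome and confidence models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting biomarker applicability with paired outcome and confidence models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gene-expression biomarkers for breast cancer — recurrence scores,
prognostic signatures, regulatory-activity scores — are usually validated
on a whole cohort, yet tumour heterogeneity means each of them is
informative only for a subset of patients. A clinician using such a score
for an individual patient has the prediction but no handle on whether the
score can be trusted *for that patient*. `appliscore` addresses this by
pairing every outcome model with a second, meta-level model:

1. The **clinical outcome prediction model (CPM)** predicts the clinical
   endpoint from the signature score plus clinical covariates and emits a
   per-patient **P-score**: the probability of pathologic complete
   response (pCR) to neoadjuvant chemotherapy in the classification
   branch, or a risk score (Cox linear predictor / survival-forest
   mortality) in the survival branch.
2. The CPM's own predictions are then scored per patient —
   correct/incorrect against observed response, or well/poorly predicted
   against the concordance decomposition described below — and the
   **predictability prediction model (PPM)** is trained to recognise,
   from clinical features alone, the patients the CPM gets right. Its
   output, the **C-score** in [0, 1], estimates the probability that the
   CPM's prediction is correct for a given patient and is interpreted as
   the biomarker's applicability to them.

The key assumption is that applicability is *clinically structured*: if
the CPM's failures were unpredictable noise, no PPM could beat chance. The
framework is therefore validated by the shape of the C-score-sorted
accuracy curve — declining accuracy with declining confidence — rather
than by the PPM's AUC alone.

```{r, eval = FALSE}
library(appliscore)
sim <- simulate_classification_cohort(n = 600, applicable_fraction = 0.5,
                                      effect_beta = 2, seed = 7)
oof <- out_of_fold_pscores(sim$cohort, sim$scores,
                           predictors = c("age", "er_status", "stage"),
                           n_trees = 1000, seed = 8)
labels <- label_classification_predictability(oof, sim$cohort$clinical)
ppm <- train_ppm(sim$cohort, labels,
                 predictors = c("age", "er_status", "stage", "subtype"),
                 n_trees = 1000, seed = 9)
curve <- sorted_accuracy_curve(predict_cscore(ppm, sim$cohort),
                               data.frame(sample_id = labels$sample_id,
                                          metric = as.numeric(labels$label
                                                              == "positive")),
                               window = 20)
```

## Models and defaults

**Random-forest backbone.** Both the classification CPM and the PPM are
random forests (`randomForest`), 10,000 trees by default with all other
hyperparameters at the package defaults. Forest accuracy is essentially
flat beyond a few thousand trees; the large default buys stable
probability estimates at the cost of fitting time, and every fitting
function takes `n_trees` so smaller forests can be used where speed
matters (the test suite uses 100–1000). The fitting contract — a
probabilistic binary classifier over a model frame — is deliberately
narrow, so another backbone could be substituted without touching the
labeling or evaluation code.

**Class balancing.** Response data are imbalanced (pCR is the minority;
the generator targets 25% prevalence), and an unbalanced classifier
drifts toward the majority class. Before every CPM and PPM fit the
majority group is randomly down-sampled to the minority size
(`downsample_majority`; all minority samples are always retained, the
seed makes the subset reproducible, and discarded samples are still
scored at prediction time). In cross-validation the down-sampling happens
inside each training fold, never touching the evaluation fold.

**Survival CPMs.** The default survival CPM is a univariate Cox
proportional-hazards model on the signature score with the Efron
approximation for tied event times; its P-score is the linear predictor.
A random survival forest (`ranger`, 500 trees) is available for
nonlinear score–risk relationships; its P-score is the ensemble
mortality (cumulative hazard summed over the event-time grid). For both,
*higher P-score = shorter predicted survival*; that direction is part of
the fit contract and is what the concordance decomposition assumes.

**Concordance decomposition.** Under right censoring only some patient
pairs can be ordered with certainty (both events; or the censored member
outlived the other's event). Overall concordance counts correctly ordered
effective pairs with half-credit for risk ties; the sample-specific
concordance c_i restricts the count to pairs involving patient i. Because
each pair contributes to exactly two patients, Σ n_i c_i = 2 (concordant
+ ½ tied), so the n_i-weighted mean of c_i equals the overall index — the
test suite asserts this identity to 1e-12 and checks the whole
decomposition against a brute-force pair enumerator. Patients with fewer
than `floor(0.2 n)` effective comparisons (inclusive threshold at the
floor, e.g. 199 of a 997-patient cohort) carry too little information and
are excluded before labeling; among the rest, c_i strictly above the
overall index means well predicted (exact equality counts as poorly
predicted — the boundary had to fall somewhere, and the conservative side
avoids inflating the positive group).

**Tie handling.** Risk ties in a pair count ½ (the Harrell convention);
equal event times with both events are effective but outcome-tied, also
½. Probeset collapse breaks exact mean-intensity ties by input order;
subtype-correlation ties resolve by the fixed order Basal, Her2, LumA,
LumB, Normal. All three tie events are reported via messages when they
occur.

**Label provenance.** Correctness labels computed from a model's fit to
its own training data are optimistic. The default provenance is
`out_of_fold`: every patient's P-score comes from a CPM trained on the
other nine folds. The `in_sample` mode uses the forest's out-of-bag
probabilities for training samples, which is the natural in-sample
analogue that does not degenerate to "everything correct". Both modes are
recorded on the labels and in the PPM's training log.

**Signature scoring and subtyping.** The generic scorer computes a
weighted mean of per-gene z-scores (weights normalised by Σ|w|);
z-scoring makes it invariant to per-gene affine transformations, and
zero-variance genes contribute zero rather than NaN. It deliberately does
not reproduce any commercial assay's rescaling — rank behaviour, not
absolute score values, is what the downstream models consume — and
externally computed scores can be imported as a drop-in replacement
(`read_scores`). Subtyping restricts to the genes shared with the
centroid profiles, median-centres each gene across the cohort, and
assigns each sample the centroid with the maximal Spearman correlation;
using ranks makes the call invariant to monotone per-sample distortions.

**Cross-validation and curves.** AUC is computed on the pooled
out-of-fold probabilities of each repeat (stratified folds, 10×10 by
default) and averaged over repeats. Drop-predictor importance is the AUC
decrease when a predictor is refit away under the same seed (note the
standard caveat: duplicated informative predictors shade each other to
near-zero importance). The sorted accuracy curve computes the running
mean of the outcome metric in decreasing C-score order (ties by sample
id) and smooths it with a centred moving average whose window truncates
at the series edges; windows default to 20 for classification
(correctness is a noisy 0/1 series) and 200 for survival (c_i is already
smooth, and survival cohorts are larger).

## The synthetic cohorts

The generators produce the structure the framework assumes, at desk
scale: age ~ Normal(55, 10), three stage levels, five molecular subtypes,
a standard-normal biomarker score, and an applicability stratum keyed to
ER status (positive with probability `applicable_fraction`). In the
classification generator the score shifts the pCR log-odds by
`effect_beta` per unit *only inside the stratum*, with the intercept
calibrated by root-finding so the marginal prevalence hits its target
(0.25 by default). The survival generator uses exponential event times
with hazard `baseline_hazard · exp(effect_beta · score)` inside the
stratum and exponential censoring (defaults 0.1 and 0.05, giving roughly
30% censoring). Subtype-calling fixtures are exact centroid copies plus a
Normal(8, 1) per-gene baseline and iid noise; the synthetic centroids are
row-median-centred so the noiseless case is exactly recoverable. All
generators are pure functions of their seed.

What the generators do *not* emulate: correlated clinical covariates,
batch and platform effects, non-proportional hazards, informative
censoring, and applicability driven by more than one covariate. Passing
tests on these cohorts show the machinery is correct and that a planted,
clinically structured applicability signal is recovered; they do not show
that any real biomarker's applicability is as cleanly structured.

A consequence worth stating explicitly: when applicability is keyed to a
*single binary* covariate, the PPM's C-score can take essentially only
two values, and its AUC is capped by the two-point distribution of
correctness — about 0.83 even when the biomarker is perfect inside its
stratum and a coin flip outside, and much less when the within-stratum
accuracy contrast is moderate. High PPM AUCs on real cohorts therefore
imply applicability structured across several clinical dimensions. The
planted-recovery tests use the idealized two-value scenario (deterministic
correctness inside the stratum); the end-to-end tests assert ordering
properties (C-scores higher in the applicable stratum, declining sorted
curves) rather than AUC thresholds, for exactly this reason.

## Numerical and design choices

- Every stochastic operation takes an explicit integer seed and restores
  the global RNG state (`withr::with_seed`); nothing depends on, or
  perturbs, the session RNG. Derived seeds are small offsets of the
  user's seed.
- Missing clinical values are `NA` throughout; each model excludes
  samples missing one of *its* variables, with a message reporting the
  count, rather than imputing or carrying an explicit "missing" level.
- Factor levels seen at training time are stored on the fit and enforced
  at prediction, so train/apply encodings cannot drift; unseen levels
  are an error rather than a silent extrapolation.
- Fold assignment draws on a canonical (sample-id-sorted) ordering, so
  cross-validation results depend on the seed but not on row order.
- Cox fitting requires at least one event and a finite coefficient;
  concordance decomposition requires at least one effective pair; PPM
  training requires both label groups non-empty. All three fail with
  explicit errors rather than returning degenerate fits.
- Problem sizes in the tests and the acceptance script (cohorts of
  200–2000, forests of 100–1000 trees, 2–5 CV repeats) were chosen as the
  smallest sizes at which the planted effects are comfortably resolved;
  the package defaults remain the full-scale settings (10,000 trees,
  10 repeats).

## Limitations

- The weighted z-score scorer is a stand-in for assay-specific scoring
  rules; analyses that need the exact commercial score values should
  import them via `read_scores`.
- Sample-specific concordance inherits Harrell-type censoring bias: the
  effective-pair filter controls the variance of c_i but not the bias
  from informative censoring.
- Drop-predictor importance is misleading under predictor redundancy (a
  documented property, demonstrated in the test suite).
- C-scores are probabilities from a balanced-trained forest and are not
  recalibrated to the unbalanced population; they are meant to rank
  patients by applicability, not to be read as calibrated frequencies.
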