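---
title: "Methods: evolutionary deep learning for predicting externalizing-disorder onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary deep learning for predicting externalizing-disorder onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ielnet` implements an end-to-end pipeline for predicting the onset of
adolescent externalizing disorders — ADHD (CBCL attention-problems
subscale), oppositional defiant disorder (aggressive-behavior subscale) and
conduct disorder (rule-breaking subscale) — from high-dimensional multimodal
tabular data, together with a synthetic cohort generator that emulates the
statistical structure of such data. This vignette is the package's account
of the modelling choices: the generative model, each pipeline stage and its
assumptions, the tunable parameters that matter, and the places where the
design was genuinely open.

## The synthetic cohort and its liability-threshold outcome model

Real data of this kind (two-wave longitudinal cohorts with parent-rated CBCL
subscale T-scores and thousands of psychosocial and neuroimaging-derived
candidate predictors) are restricted-access. `generate_cohort()` therefore
simulates a cohort with the features of that structure the pipeline actually
relies on:

* a **psychosocial block** of mixed nominal, ordinal and continuous
  features with feature-specific missingness rates drawn uniformly on
  `[0, missing_rate_max]` (MCAR by default; an MAR toggle tilts row odds by
  age, since the imputation method is reported to be robust to the
  missingness pattern, and MCAR keeps the ground truth analysable);
* a **neural block** of complete continuous features — emulating
  quality-controlled, pipeline-processed imaging metrics, which arrive
  complete and pre-curated;
* **family structure** (families of size 1–3 governed by `sibling_rate`),
  ages 107–132 months, and binary sex, exercising the oldest-sibling
  inclusion rule and age/sex matching;
* three subscale **T-scores at two waves**, normed to mean 50, SD 10.

The follow-up score for each subscale is generated by a liability-threshold
model: with `z_signal` a standardized equal-magnitude (random-sign) linear
combination of `n_informative` planted continuous features,

$$T_1 = \mu + \sigma\left(\lambda z_{signal} + \sqrt{1-\lambda^2}\,
z_{noise}\right), \qquad \lambda = \frac{\beta}{\sqrt{1+\beta^2}},$$

where `beta = effect_size`. Because `z_signal` and `z_noise` are
standardized, the marginal distribution of `T_1` is N(50, 10) for every
effect size, so the case prevalence at the borderline-clinical threshold
T ≥ 65 is the normal tail `1 - pnorm(1.5)` ≈ 6.7% by construction. The
baseline score shares the wave-1 liability with correlation `rho_waves`
(default 0.5, a typical two-year stability for CBCL subscales). A
liability-threshold formulation was chosen because the analysis itself
thresholds normed T-scores; it makes `effect_size` interpretable and the
oracle performance computable. The documented "strong" default is
`effect_size = 2` (λ ≈ 0.894): a logistic regression on the true planted
features alone then separates held-out cases from non-cases with AUROC
well above 0.85, which is what the planted-recovery tests assume.

What the generator deliberately does **not** emulate: realistic covariance
among neuroimaging metrics (features are independent), instrument-specific
item structure, twin genetics, and site effects. Tests that pass on this
cohort therefore certify the pipeline's mechanics — leakage-free
preprocessing, selection, optimization, evaluation — not its behaviour under
correlated or confounded real data.

## Case definition and sample construction

A participant is a **case** for a subscale iff the T-score is at or above
the threshold (default 65, the borderline-clinical cut-point; `>=` so
exactly 65 is a case). **New-onset** cases meet the threshold at follow-up
but not at baseline; **prevailing** cases meet it at follow-up regardless.
Targets are never imputed — a missing T-score is an error.

The unrelated-participant rule keeps one child per family, the oldest by
age in months, with age ties broken by the lexicographically smallest id (a
determinism decision). The 70/30 train/test partition is drawn **before**
any preprocessing or thresholding, so no fitted statistic ever sees a test
row. Within each partition independently, the control pool is first
restricted, per sex, to the non-cases with the lowest follow-up scores on
the target subscale — exactly as many as there are cases of that sex, the
literal reading of "lowest possible scores" — and each case is then
greedily matched within that pool to a control of exactly the same sex with
the nearest age in months (ties: lower score, then smaller id). Drawing
controls from the extreme-low tail, rather than from arbitrary non-cases,
is what gives the case-control contrast its strength; matching on age and
sex happens inside that restricted pool. For new-onset targets the pool is
additionally restricted to
participants who are non-cases at both waves; a control who was a baseline
case would contaminate the onset contrast. This extra screen is an
assumption the case definition itself does not force.

## Preprocessing

Stages run in a fixed order — missingness filter, one-hot encoding, outlier
trimming, min-max scaling, NNMF imputation, optional feature agglomeration —
mirroring the narrative order of the analysis the package re-implements:

* **Missingness filter**: features with *more than* 35% missing are
  discarded (a feature at exactly 35% survives).
* **One-hot**: nominal *and* ordinal variables expand to one indicator per
  observed level; a missing source value propagates to all derived columns.
  More than 50 observed levels raises an error (almost always a mis-tagged
  id column).
* **Trimming** clips continuous values into mean ± 3 SD, with the moments
  computed from observed values of the current partition. Clipping
  (winsorizing) rather than deletion was chosen because deletion would
  create new missingness that nothing downstream re-imputes; this is an
  open interpretation flagged here.
* **Min-max scaling** maps each feature to `[0, 1]`; constant features map
  to 0. Binary indicators are unchanged by construction.
* **NNMF imputation** fills missing entries from a rank-`r` non-negative
  factorization fitted by multiplicative updates that mask missing entries
  out of the cost (`rank = 8` by default; `rank = "auto"` picks from
  {2, 4, 8, 16} by masked-holdout reconstruction error). Observed entries
  are never altered; imputed values are clipped to `[0, 1]`. The rank-1
  masked completion of a rank-1 matrix is exact, which the tests use as an
  oracle.
* **Agglomeration** (optional) reduces grouped psychosocial items to
  cluster means via Ward-linkage hierarchical clustering, after imputation.
  The cluster count per instrument is data-dependent in real use, so it is
  exposed as configuration rather than guessed.

Neural features bypass everything except min-max scaling. Each partition
refits its own statistics — the deliberately unusual "separately in train
and test" choice of the original analysis is the default, with a
conventional fit-on-train toggle (`fit_on_train = TRUE`) available because
the default surprises most practitioners. Model features are aligned to
test columns by name, with absent columns (e.g. a one-hot level unobserved
in the test partition) filled with 0.

## Coarse feature selection

A permissive filter retains any feature with a non-zero estimated
relationship to the binary target: a chi-square statistic for categorical
features, an ANOVA F for continuous features, and a mutual-information
estimate for all (retained iff MI > 1e-6 *or* the statistic is positive;
constants always drop). This is literal non-zeroness, not a significance
test — most features survive, as intended. MI for continuous features uses
a nearest-neighbour estimator (k = 3 by default) for a 1-D variable against
a discrete label; categorical MI is the contingency-table plug-in.

The surviving features enter a **linear LASSO on the 0/1 target** (the
shrinkage step is linear, not logistic, following the analysis being
re-implemented), scored at each penalty α by a Gaussian-RSS BIC:
`p_nz ln(n) + n ln(RSS/n)` with `p_nz` the nonzero-coefficient count. The
BIC form is our choice; none was given. Two numerical guards matter at
small n: a (near-)saturated fit (`p_nz ≥ n − 1` or RSS ≈ 0) has an
unbounded Gaussian likelihood, so its BIC is set to +∞ rather than letting
saturation always win. α is tuned by the evolutionary engine over a
log-uniform range `[1e-4, 10]` with the LASSO BIC as fitness; the selected
set is the nonzero-coefficient features at the best α.

## The evolutionary engine (IEL)

One genome holds a hyperparameter vector (learning rate in
`[1e-5, 0.01]`, Adam moment decays β₁ and β₂ each in `[0.9, 0.999]`) and,
when feature subsets are evolved, an ordered subset of 2–50 feature ids.
Each generation of 100 genomes is ranked by BIC — **lower is better**; the
engine minimizes the BIC throughout (the fitness is explicitly an
information criterion, and minimization is the stated goal of the procedure
this engine re-implements; stray wording to the contrary is resolved in
favour of standard BIC semantics). The best 40 are paired randomly without
replacement and recombined — hyperparameters arithmetically averaged
(geometrically for log-scaled ranges), feature subsets crossed at the
midpoint: the child takes the first half of one parent's subset and the
last half of the other's, de-duplicated and padded/truncated into bounds.
The next 20 are mutated: one hyperparameter shifts by its mutation step
(learning rate 1e-4, β's 1e-3) with random sign, clipped to range, and with
probability 0.5 one feature id is swapped for a fresh pool feature (the
feature-mutation operator is unspecified in the source procedure; a single
swap is the minimal analogue of the hyperparameter shift). The bottom 40
are discarded and 60 fresh random genomes complete the next generation.
Children are not protected from later replacement; the best-ever genome is
tracked separately, so the incumbent trace is non-increasing by
construction.

The search stops when the best BIC improves by less than a relative δ
(default 1e-3) across the trailing window of W generations (default 10).
The engine then computes per-feature importances over the final elite —
softmax(−BIC)-weighted selection frequencies, so a feature in every elite
genome scores 1 — and the elbow of the best-BIC-versus-subset-size curve
(maximum perpendicular distance to the chord after min–max normalizing both
axes; collinear curves fall back to the smallest size at the best BIC). The
**warm restart** pool keeps features with importance at or above the elbow
importance plus two standard deviations of the importances. Three details are
our resolutions of genuinely open points: the softmax is tempered by the
spread of the elite BICs (so the weights grade across the elite instead of
collapsing onto the single best genome whenever raw BIC gaps are large);
the standard deviation is taken over features' importances (not over
generations); and the threshold is capped at the second-highest importance,
so the restart pool always retains at least the two most important features
— otherwise the +2 SD shift can exceed every importance and make the
prescribed restart unreachable. Phase 2 re-initializes 50 genomes over the restart pool
(20 recombination parents, 10 mutants, 30 fresh per generation) and runs to
plateau again. If fewer than two features clear the threshold the restart
is skipped with a warning.

All randomness flows from one seed; with a deterministic fitness callback
the entire run, including both phases, is bit-reproducible.

## The neural estimator and its BIC fitness

The classifier is a fixed feed-forward architecture: three hidden layers of
300 rectified-linear units and a 2-unit softmax output, trained with AdamW
(decoupled weight decay 0.01 on weights only, batch size 32, at most 100
epochs by default) using the genome's learning rate and moment decays.
Early stopping monitors validation loss with patience 3 and restores the
best-epoch weights. The implementation is plain base-R matrix code — the
architecture is small and fixed, and a few dense GEMMs per batch are all
that is needed.

Fitness of a genome is computed by stratified k-fold cross-validation with
**k = ⌈n/d⌉** (sample size over the genome's feature count), clipped into
`[2, min(20, minority-class count)]`; the upper cap is our decision — the
rule alone would demand 100 folds for a 2-feature model on 200 rows. Each
fold's training rows are split 80/20 (stratified) for early stopping, so
the held-out fold contributes only to the fitness likelihood. The summed
held-out log-likelihood L̂ over all n rows yields `BIC = p ln(n) − 2 L̂`.

The complexity term `p` is genuinely underdetermined: for the full
trainable parameter count (the `"full"` mode, and the worked-example
convention: d = 10 gives p = 184,502), one extra input feature costs
`300 ln(n)` BIC — far more than any attainable likelihood gain at
case-control sample sizes, so subset evolution degenerates to two-feature
genomes. Final models of the re-implemented analysis contain 4–9 features,
which is only consistent with a complexity term commensurate with
per-feature likelihood gains. The pipeline therefore uses
`param_mode = "n_features"` (p = d) for its fitness while `cv_fitness()`
defaults to the full count; both are monotone in d for the fixed
architecture, and the mode is a single switch.

Two further stabilizers: probabilities are clipped at 1e-12 before taking
logs, and all genomes within one experiment share a single cross-validation
seed (common random numbers) — with per-genome seeds the winner of the
evolutionary search is biased toward genomes with lucky fold draws rather
than genuinely better subsets.

## Evaluation and interpretation

Held-out metrics use the 0.5 probability threshold (a probability of
exactly 0.5 classifies as a case). The ROC curve is the tie-aware
staircase whose trapezoidal area equals the Mann–Whitney
probability-of-correct-ranking estimator with half credit for ties; the
test suite cross-checks it against both an O(n²) pairwise oracle and the
pROC implementation. Accuracy, precision and recall follow the standard
confusion-count identities, reported in percent.

Feature importances are model-agnostic Shapley values of the class-1
probability: the value of a coalition is the mean model output over a
background set (up to 100 k-medoids-summarized training rows) with
coalition features taken from the explained row. Estimation is by
permutation sampling — each permutation's marginal contributions telescope,
so additivity (base value + Σφ = model output) holds exactly per row — with
exact enumeration of all 2^d coalitions used automatically for d ≤ 10–12.
Explanations are computed on held-out test rows, matching the convention of
reporting importances for final models after generalization testing.
Group-level importance is the mean |φ| per feature across participants;
per-experiment mean importance is the mean of the group importances; and
the accuracy-importance analysis reports the Pearson correlation (and its
square) between per-experiment accuracy in percent and mean importance,
with log-accuracy emitted for plotting only.

## The experiment grid and problem sizes

The full design is 12 experiments: three subscales × {new-onset,
prevailing} × {multimodal, neural-only}, each with an independent seed
derived from the master seed by a stable string hash. The neural-only scope
restricts the candidate pool to neural-tagged features before coarse
selection. Failures are contained per experiment, and the correlation is
computed across completions.

Two configurations ship. `pipeline_config()` holds study-scale settings
(population 100, restart 50, up to 400 generations). `smoke_config()` is
the package's reduced profile used by the test-suite and example runs:
population 20 (restart 10), plateau window 4, at most 14 + 6 generations,
20 training epochs, 3-fold cap, and a fine-selection pool capped at the 15
selected features with the largest univariate coefficients. The cap keeps
the search density per candidate feature comparable to the study-scale
profile, whose ~40,000 evaluations per experiment are three orders of
magnitude beyond the smoke budget; univariate rather than LASSO
coefficients rank the pool because the LASSO splits weight among correlated
features. Smoke-scale planted-recovery runs use a 600-participant cohort
with 400 features (40 neural), 5 planted predictors at the strong effect
size, and the prevailing-case target, which yields balanced samples of
roughly 50–60 training and 16–24 test rows.

## Known limitations

* The Gaussian-RSS LASSO BIC and the network BIC are model-selection
  heuristics, not calibrated likelihoods; their absolute values are only
  comparable within a stage.
* At smoke scale the per-genome fitness is noisy (tiny folds, tiny
  validation splits); common random numbers mitigate but do not remove
  winner's-curse effects in the selected genome.
* Independent per-partition preprocessing (the faithful default) can
  produce test matrices whose one-hot levels differ from training; the
  name-based alignment fills such columns with 0, which slightly biases
  predictions toward the majority pattern for rare levels.
* The generator's independent features make coarse selection easier than
  on real, collinear data; planted-recovery results should be read as
  mechanism checks, not effect-size claims about real cohorts.
* At very small balanced samples (tens of rows, as arise from a
  600-participant cohort at ~6.7% prevalence), BIC-guided subset selection
  is parsimonious by construction: once two or three planted features are
  in a genome, the marginal cross-validated likelihood of the remaining
  ones falls below the per-feature `ln(n)` cost plus the training-noise
  floor, so final genomes typically carry a *subset* of the planted
  features (with held-out AUROC often high regardless). Full recovery of a
  planted set in the final genome is only a reliable expectation at
  several hundred balanced rows and larger search budgets.
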