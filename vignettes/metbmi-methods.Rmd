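---
title: "Metabolome-informed BMI and bidirectional mediation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolome-informed BMI and bidirectional mediation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models each
stage fits, the assumptions they lean on, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical choices made where the design was genuinely open, and the known
limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The metBMI framework

A penalized linear model predicts BMI from log-scale circulating metabolite
intensities. The pipeline has five fixed stages:

1. **Pre-filter.** Metabolites enter the model only if their Spearman
   correlation with BMI exceeds |ρ| > 0.1 *and* survives Benjamini–Hochberg
   at q < 0.05 (`select_bmi_metabolites()`). Both gates default on; the
   significance gate can be disabled with `q_threshold = 1` for a pure-ρ
   rule.
2. **Balanced sampling.** Six strata — {female, male} × {BMI 18.5–24.9,
   25–29.9, ≥ 30 kg m⁻²} — each contribute, without replacement, as many
   participants as the smallest stratum holds. A smallest stratum of 129
   therefore yields a pool of exactly 774. Participants below BMI 18.5 fall
   outside all strata and are routed to the non-test set.
3. **Split.** A seeded 75/25 train/test split, stratified on the six
   strata; the extended test set is the test set plus all non-pool samples.
4. **Fit.** Ridge regression (lasso available) with the penalty chosen by
   10-fold cross-validation minimising mean squared error over a 100-value
   log-spaced grid with minimum ratio 10⁻⁵. The printed penalty range in
   the source methods ("length λ = 100, range 10⁻³ to 10⁻⁵") is ambiguous
   between an absolute range and a minimum-ratio specification; the
   minimum-ratio reading is implemented because an absolute range on
   standardized data is scale-fragile. Hold-out R² on the untouched test
   set is the performance figure.
5. **Residual phenotyping.** metBMI is predicted for the whole cohort; the
   residuals of `metbmi ~ age + sex + bmi` (ordinary least squares on the
   full cohort — the residualization sample is not pinned by the source
   text, so the full cohort is used and documented) define the groups:
   residual < −2.5 kg m⁻² → LmetBMI, residual > +2.5 → HmetBMI, all others
   (including exact boundary values — the inequalities are strict) keep
   their WHO BMI class. Thresholds are in metBMI units, not SD units, and
   are exposed as configuration. The rare participant below BMI 18.5 is
   folded into "normal weight" so the five classes partition the cohort.

**Assumptions.** The metabolome–BMI relation is treated as linear on the
log scale; the residual is meaningful only insofar as the OLS adjustment
removes age, sex and BMI linearly (orthogonality of the residuals to those
three covariates is a property of OLS and is asserted to |r| < 10⁻⁸ in the
tests).

## 2. Variance explained by nested cross-validation

`nested_cv_r2()` estimates how much of a target's variance one omics layer
explains, without letting penalty selection peek at evaluation data: each of
10 outer folds is held out while the remaining nine run an inner 10-fold
grid search; the refit model predicts the untouched fold. Choices that the
source text leaves open, pinned here:

* Hold-out R² uses the held-out fold's own mean in the denominator, so a
  mean-only predictor scores exactly 0 and negative values are reported
  as-is.
* Outer folds are stratified on target deciles (variance reduction for
  skewed targets).
* Inner-CV ties break toward the larger penalty (more regularization).
* Features constant on the data are dropped with a log entry; features are
  standardized inside the penalized fit on training folds only.

When the target is itself an omics feature, `exclude_self_layer()` removes
the entire layer containing it (a metabolite is never predicted from the
metabolome). Layer comparison uses two-sided Wilcoxon rank-sum tests on the
per-fold R² vectors, BH-corrected, summarised as a compact letter display
computed from the maximal cliques of the not-significantly-different graph.

## 3. Outcome risk models

Binary cardiometabolic outcomes are modelled by binomial logistic
regression, adjusted for age and sex, in three specifications per outcome:
BMI only, metBMI only, and nested (both). Predictors are standardized to
unit SD on the listwise-complete analysis sample of the model at hand, so
odds ratios are per 1 SD; nested and single-predictor models fitted through
`fit_outcome_model_set()` share one analysis sample and hence one scaling.
Wald CIs use z = 1.96. Convergence is IRLS to a 10⁻¹⁰ relative tolerance;
separation is declared when a standardized coefficient passes |15|, and
perfectly collinear predictors abort rather than silently aliasing. The
added value of metBMI beyond BMI is a likelihood-ratio test: deviance
difference referred to χ² with the parameter-count difference as degrees of
freedom. Identical models are allowed (statistic 0, p = 1); the extended
adjustment set (WHR, lipids, blood pressure, glucose, statin use) is taken
from whatever of those columns the data contains and logged verbatim.

## 4. Panel selection

The metabolite space is reduced in three stages:

1. **Shadow-feature (all-relevant) screening.** Every candidate gets a
   permuted shadow copy; a random-forest regressor scores the augmented
   design and a feature registers a *hit* when its importance beats the
   best shadow. Two-sided binomial tests on hit counts — Bonferroni-
   corrected across the features still undecided — confirm or reject;
   unresolved features are tentative. The importance is the **z-scored**
   (SE-scaled) permutation importance: raw permutation importance lets
   persistent in-sample spurious correlations beat the shadow maximum and
   produce false confirmations on pure-noise data, while scaling restores a
   clean null without losing planted features (the test suite asserts zero
   confirmations on null designs at n = 500, p = 50 and full recovery of
   planted features). A ridge-coefficient importance source can be plugged
   in (`importance = "ridge"`), since the run count in the source methods
   (999) is stated without naming the importance source.
2. **Sparse stability.** Ten seeded 80% resamples each fit a lasso with a
   cross-validation-chosen penalty; a feature's frequency is the fraction
   of resamples selecting it. The penalty is the one-standard-error choice:
   the CV-MSE minimiser routinely admits noise features, which defeats the
   purpose of a stability stage, whereas the 1se rule keeps null
   frequencies near 0 and true features at 1.0 (asserted in the tests:
   noise frequencies ≤ 0.2, a target-equal feature at 1.0).
3. **Assembly.** The default panel is the confirmed set, ranked by
   stability frequency then |ρ| with the target. The source description of
   its final panel is a union of three sources; `rule = "union"`
   additionally admits high-frequency tentative features. The panel and the
   full candidate set are both refit through the ridge metBMI pipeline on
   the original split, and the two hold-out R² values are reported side by
   side.

**Known limitation.** When the signal-bearing features are strongly
correlated (in the default generator all 20 informative metabolites load on
one latent factor, pairwise r ≈ 0.65), one to three of them are
informationally redundant given their siblings: permuting such a feature
barely degrades the forest, its hit rate hovers near one half, and it
finishes tentative rather than confirmed. Panel *recall* of planted
features therefore lands around 0.90 rather than above 0.95 on such data,
while panel *retention* of explanatory power is unaffected (the confirmed
siblings carry the same information). This is a property of all-relevant
selection under redundancy, not an implementation defect.

## 5. The bidirectional mediation engine

For exposure x, mediator m and outcome y, two ordinary-least-squares models
are fit: `m = α₀ + a·x` and `y = β₀ + c′·x + b·m`. The unstandardized
indirect effect (ACME) is a·b, the direct effect (ADE) is c′, and
ACME + ADE equals the total effect exactly — a linear-model identity
asserted to 10⁻⁸ on every dataset. No covariates enter the mediation fits
by default, matching the stated outcome model `y = x + m`. Uncertainty
comes from nonparametric case resampling: rows are resampled jointly for
both regressions (the cited tool offers several schemes; case resampling is
the distributionally robust choice), confidence intervals are percentile,
and two-sided p-values are `2·min(Pr(draw ≤ 0), Pr(draw ≥ 0))` floored at
`2/(n_boot + 1)`. If a bootstrap draw makes the outcome design singular
(mediator exactly collinear with exposure), the shared effect is attributed
to the mediator (b from `y ~ m`, c′ = 0) — the tie-break that makes the
noiseless chain `m = 0.5x, y = 0.8m` yield ACME exactly 0.40 and ADE 0.

Every candidate triple is evaluated in three grids: direct
(microbiome → metabolite → phenotype), reverse1
(microbiome → phenotype → metabolite) and reverse2
(phenotype → metabolite → microbiome). ACME p-values are BH-adjusted within
each grid (the source names grid-specific FDR quantities, so adjustment is
not pooled across grids); ADE p-values are additionally adjusted within
reverse2, the only grid whose direct effect enters the rules. Per-triple
seeds derive deterministically from the master seed and the triple's ids.
The "P value-ADE > 0.05" clause in the first rule is read as the
reverse2-grid direct effect (phenotype → bacteria), consistent with its
parenthetical; the "and/or" in the phenotype→microbiome rule is read as
inclusive-or, with the subclass (mediated / direct / combined) recording
which branch fired.

Candidate triples come from `prefilter_candidates()`: pairwise Spearman
between the three feature sets, BH within each set pair, a feature retained
only with at least one significant cross-set partner at |ρ| ≥ 0.1. Because
per-pair adjustment runs three step-up families, a fully null cohort
retains at least one feature in roughly 3 × 5% of seeds; the
`bh_scope = "pooled"` option adjusts across all cross-set tests at once and
caps that at 5% overall. The per-pair default follows the stage's stated
contract; the pooled option exists for users who need the stricter global
null guarantee.

**Known limitation — directional identifiability.** For a genuine linear
chain x → m → y, the reverse-ordering ACMEs are non-zero *population*
quantities, not artefacts: with a = b = 0.5 and unit noise, the reverse1
ACME is ab·b·var(ε_m)/var(y|x) = 0.10 and the reverse2 ACME ≈ 0.19, against
a forward ACME of 0.25. At any sample size where the forward test has
power, the reverse tests do too, so the exclusion rules (which demand raw
reverse p > 0.05) leave strong clean chains *unclassified in either
direction*. The rules therefore select pathways in the near-threshold power
regime — forward evidence present, reverse evidence absent — and a
simulation that plants strong noiseless chains will see recovery rates near
zero by construction. The test suite asserts exactly this behaviour, and
the acceptance report includes the recovery rate as computed. Users should
read classified linkages as "directionally consistent candidates", not as
causal discoveries; sensitivity analysis for confounding is out of scope.

## 6. The synthetic cohort generator

`generate_cohort()` emulates the study conditions: n = 1,408 participants
(sex balanced exactly, ages uniform 50–65), BMI with mean 27 and SD
4.0 kg m⁻² clipped to [18, 46], a metabolome of 300 log-scale features of
which 20 carry the BMI signal through one latent factor, a zero-inflated
compositional species layer (per-feature prevalence uniform in
[0.10, 0.90], depth-multinomial counts), gut-module and proteome layers,
and binary outcomes from a logistic model on standardized BMI and the
metabolic-deviation score with stated per-SD log-odds.

Numerical choices:

* **Exact planted R².** BMI = mean + Σⱼ wⱼ·metaboliteⱼ + ε with the weights
  scaled so the population R² of OLS on the informative metabolites equals
  the request exactly; ε is a *shifted lognormal* (mean 0, required
  variance, τ = 0.4), which gives BMI its right-skewed marginal without
  breaking the linear-plus-independent-noise decomposition. Clipping to
  [18, 46] touches ≈ 1% of draws and moves the achieved R² by well under
  the ±0.02 oracle tolerance (checked by `oracle_bmi_r2()` on 100,000-
  sample oracle draws).
* **Default planted R² = 0.39** — the hold-out regime of metabolome BMI
  models at this cohort size. With BMI SD 4.0 this implies a residual SD of
  √(16·0.39·0.61) ≈ 1.95 kg m⁻², which puts ≈ 10% of the cohort in each
  residual tail at the ±2.5 cuts; both figures were fixed analytically
  before any test was run.
* **Metabolic deviation for outcomes** is the metabolome-driven BMI
  component orthogonalized against BMI in the population, standardized —
  the generator-side analogue of the metBMI residual, available before any
  model is fit.
* Planted mediation triples regenerate the mediator as a·x + noise and the
  outcome as b·m + c′·x + noise, recording (a, b, c′) in the truth file.
  Exposure values are used exactly as stored in their layer; transform to
  CLR first if a CLR-scale exposure is intended.
* The truth record is written next to the cohort (`truth/truth.json` in
  pipeline runs) and is never read by any inference stage.

What the generator does **not** emulate: phylogenetic correlation among
species, longitudinal sampling, batch effects, assay drift, non-linear
metabolome–BMI relations, and missingness mechanisms. Passing tests
therefore show that the *algorithms* recover what was planted under clean
conditions; they do not certify performance on real cohort data.

## 7. Problem sizes and seeds

All analyses are seeded; one master seed fans out to per-stage seeds via a
small deterministic hash of the stage label (`derive_seed()`), so adding a
stage never perturbs another stage's randomness. The verification runs use
desk-scale sizes chosen once: CI coverage with 200 replicates at n = 500
and 500 bootstrap draws; linkage recovery over 20 seeds (10 triples,
n = 800, 499 draws) and null grids over 50 seeds (100 triples, n = 500,
199 draws — p-value floors 0.004 and 0.01, far from the 0.05 decision
boundaries); nested CV at n = 1,400 with 300 metabolites; LRT calibration
with 1,000 simulations at n = 500; panel selection at n = 800 with 300
metabolites. Rarefaction defaults to the configurable depth recorded in the
run config (2.2 × 10⁷ reads in the cohort setting); tests exercise small
depths where exhaustive enumeration is possible.
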