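---
title: "Staging liver fibrosis from the urinary steroid metabolome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging liver fibrosis from the urinary steroid metabolome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steroidstage)
```

## The problem

Non-alcoholic fatty liver disease (NAFLD) is staged histologically by
fibrosis grade, from F0 (no fibrosis) to F4 (cirrhosis), on the Kleiner
system. Biopsy is invasive and samples a tiny fraction of the liver, so
non-invasive staging markers matter clinically. Because the liver is the
main site of steroid hormone metabolism — 11β-hydroxysteroid
dehydrogenase type 1 (11β-HSD1) regenerates cortisol from cortisone, and
the A-ring reductases inactivate cortisol to tetrahydro-metabolites
excreted in urine — the urinary steroid metabolome is a candidate
functional readout of liver state. This package implements a complete
staging pipeline over a 32-metabolite GC-MS urinary steroid panel:
preprocessing, enzyme-activity ratios, serum comparator scores, a
prototype-based classifier with an adaptive metric (GMLVQ), repeated
train/test validation with ROC/AUC, and backward reduction to a compact
steroid signature. A synthetic cohort generator emulates the statistical
structure of a biopsy-staged case-control study, so every stage of the
pipeline is testable end to end without patient data.

## Preprocessing

Spot-urine concentrations (μg/L) are normalised to grams of urinary
creatinine (`creatinine_correct`): μg/g = μg/L × 100 / creatinine
(mg/dL), since 100 mg/dL = 1 g/L. Creatinine is excreted at a roughly
constant rate, so this adjusts for urine dilution. An uncorrected mode
(per litre of urine) is available throughout via `uncorrected = TRUE`
for sensitivity analyses.

Corrected concentrations are log10-transformed. Values reported as 0
(below the assay detection limit) are floored at half the smallest
positive value of each metabolite (`log10_transform`), computed on
training data only; flooring preserves subjects rather than dropping
them. Features are then z-scored with the population-SD convention
(divide by n), fitted on the training split and applied unchanged to
held-out data (`zscore_fit_apply`). The population convention is a fixed
deterministic choice; at study sample sizes the difference from the n−1
convention is immaterial, but exact tests need one convention.

Enzyme activities are computed on corrected, non-log concentrations
(`compute_ratios`): 11β-HSD1 activity = (THF + 5αTHF)/THE, A-ring
reductase activity = 5αTHF/THF, and total glucocorticoid output as the
sum of the 11 cortisol/cortisone metabolites in
`total_f_metabolites()`. Ratios cancel the per-subject creatinine
factor, so they are identical in corrected and uncorrected mode (this is
property-tested). A zero denominator yields a flagged `NA`, never an
aborted batch.

The covariate-augmented model (`covariates = c("age", "bmi")`) appends
age and BMI as additional features; they pass through the same
train-only z-scoring as the steroids.

## Serum comparator scores

Five established serum/clinical scores serve as comparators
(`apri`, `fib4`, `ast_alt_ratio`, `nfs`, `bard`), computed exactly from
their published coefficients. Two conventions are fixed here: the AST
upper limit of normal defaults to 40 IU/L (configurable), and BARD
thresholds are strict inequalities (BMI > 28, ratio > 0.8). FIB-4 is
implemented in its established form, age × AST / (platelets × √ALT),
with the square root of ALT in the *denominator*; source descriptions of
FIB-4 occasionally typeset the √ALT factor ambiguously as a
multiplication, which would not be the validated index.

## GMLVQ: prototypes with an adaptive metric

Each class is represented by a prototype vector w (default: one typical
steroid profile per disease stage, initialised at the class-conditional
mean plus seeded jitter of SD 0.01 z-units). Dissimilarity between a
profile x and a prototype is the quadratic form

d(w, x) = (x − w)ᵀ Λ (x − w),  Λ = ΩᵀΩ,

with Ω a full (unconstrained) d×d matrix learned jointly with the
prototypes. Λ is symmetric positive semi-definite by construction; its
diagonal, normalised to trace 1, quantifies each metabolite's importance
to the classification (`gmlvq_relevances`).

Training minimises Σᵢ φ(μᵢ) with μ = (d_J − d_K)/(d_J + d_K), where d_J
is the distance to the closest prototype of the sample's own class and
d_K to the closest wrong-class prototype. With the default φ = identity
each term lies in [−1, 1] and μ < 0 exactly when the sample is
correctly classified; a sigmoid transfer is available. Gradients of the
cost with respect to every prototype and every Ω entry are analytic and
verified against central finite differences.

Numerical choices:

- **Batch gradient descent with step halving** (default): a proposed
  step that would increase the cost is halved until it does not, so the
  per-epoch cost log is non-increasing and training is fully
  deterministic given the seed. A seeded stochastic (sample-by-sample)
  mode is available.
- **Trace renormalisation after every accepted update**: Ω is rescaled
  so trace(ΩᵀΩ) = 1. The relative-distance cost is invariant under this
  rescaling, so renormalisation never undoes progress; it prevents the
  metric from degenerating.
- **Step sizes**: prototype step 0.5, metric step one tenth of that,
  multiplicative decay 0.99/epoch, 60 epochs. These defaults converge
  well on z-scored steroid panels of the size simulated here; all are
  exposed in `gmlvq_train_config()`.
- **Degenerate samples**: a sample coinciding with prototypes of both
  classes (d_J + d_K = 0) contributes 0 with a logged warning.
- **Ties**: prediction ties break deterministically to the lowest class
  label in sort order and are flagged.

For binary contrasts the ROC statistic is the signed relative distance
(d_neg − d_pos)/(d_neg + d_pos) ∈ [−1, 1] (`gmlvq_score`): +1 at a
positive-class prototype, 0 on the decision boundary, antisymmetric
under swapping the arms, and thresholding at 0 reproduces `predict`.
`gmlvq_project` emits 2-D coordinates along the two leading eigenvectors
of Λ (scaled by the square roots of the eigenvalues) for external
plotting; eigenvector signs are fixed deterministically, and a rank-1
metric zero-fills the second coordinate with a warning.

## Validation

`repeated_split_validation` repeats a stratified train/test split
(default 10% held out, 100 splits; smaller settings are used in the
package's own tests, see below). Detection floors, z-scoring and the
model are fitted on the training subjects only; split membership is
drawn from the labels and the seed before any value is inspected, so
leakage is excluded by construction (and guarded by a test that poisons
held-out values and asserts identical training logs). Per-split test
AUCs are summarised by their mean, a distribution-free 95% interval
from the 2.5/97.5 percentiles of the per-split AUCs, and a pooled ROC by
vertical averaging on a 101-point FPR grid. Percentile intervals (rather
than DeLong) match the repeated-validation design; the exact resampling
scheme of the study this emulates is not public, so split count and
test fraction are exposed parameters.

The ROC itself is a threshold sweep over unique score values with
trapezoidal integration, which makes the AUC equal to the Mann-Whitney
concordance probability with half credit for ties — an identity the
test suite checks to 1e-12 against exhaustive pair enumeration.

Group differences in individual metabolites or ratios use the
tie-corrected Kruskal-Wallis test with Dunn's pairwise z-tests
(`group_compare`); the pairwise p-values are Bonferroni-corrected over
the pairs, a conventional choice where the emulated analysis does not
state its correction.

## Panel reduction

`backward_eliminate` removes one steroid per round — the one with the
smallest mean relevance across splits — and re-validates after every
removal (sequential mode, the default; a fixed-rank mode prunes against
the initial ranking instead). Averaging relevance across splits
stabilises removal against split noise. Covariates, when enabled, are
part of every model but exempt from removal, which defines the
reduced-panel covariate model. The trajectory records the mean AUC and
CI at every panel size.

## The synthetic cohort generator

`cohort_spec()` defines the study conditions; `generate_cohort()` is a
pure function of the spec (bit-identical regeneration under the same
seed). The default emulates a secondary-care case-control design: 106
controls, 39 early-fibrosis (F0-F2) and 82 advanced-fibrosis (F3-F4)
biopsy-staged NAFLD patients, and 48 alcohol-related cirrhosis
patients.

- **Steroids** are normal on the log10 scale (SD 0.25 log10 units
  within class, about a 1.8-fold coefficient of variation) and
  exponentiated, guaranteeing positivity and matching the log-transform
  assumption of the analysis. Baseline levels span the physiological
  abundance range, from mg/L glucocorticoid tetrahydro-metabolites down
  to trace androgens near the 1 μg/L detection floor; simulated values
  below the floor are reported as 0, exercising the preprocessing
  floor. The default panel comprises the 26 metabolites named in the
  enzyme-activity formulas, the glucocorticoid total and the
  discriminatory rankings, padded to 32 with six standard GC-MS panel
  steroids; the padding is configurable.
- **Class signal** enters as additive shifts of the log10 means of the
  ranked discriminatory metabolites per contrast, in units of the
  within-class SD, decaying with rank (1.1 down to 0.5 for the early-
  vs-advanced contrast). Contrasts against controls are encoded as
  negated shifts of the control class itself, so that each NAFLD stage
  contrast is discriminated by its own ranked list rather than by
  spill-over. An additional advanced-fibrosis shift raises
  5α-tetrahydrocortisol and lowers tetrahydrocortisone, so both
  glucocorticoid activity ratios rise in F3-F4 by construction. These
  sizes give a mean staging AUC of about 0.92 over seeds, matching the
  performance regime the design emulates.
- **Covariates and chemistry** are drawn normally per class from the
  demographic table of the emulated design (early fibrosis younger and
  heavier, advanced fibrosis older with lower platelets and higher
  AST), truncated to plausible ranges; values the design reports only
  for patients use normal-range clinical defaults for controls. By
  construction mean FIB-4 is higher in F3-F4 than F0-F2.
- **Alcohol-related cirrhosis** reuses the F4 parameterisation plus its
  own shift on a configurable androgen-dominated subset, so aetiology
  separation is present but imperfect.
- **NAS scores** are sampled independently of the steroid signal,
  mirroring the fact that steroid profiles stage fibrosis rather than
  inflammatory activity.

What the generator does *not* emulate: between-metabolite biological
correlation beyond the shared creatinine factor, age/sex effects on
steroid output, assay batch effects, or missingness. Passing tests on
these cohorts therefore demonstrate correctness of the algorithms and
the leakage-free harness, not clinical performance on real urine.

### Two instructive properties of the simulated data

First, *creatinine correction couples all metabolites*: dividing every
concentration by the same noisy creatinine adds a shared dilution factor
on the log scale (SD ≈ 0.22 log10 units at the default creatinine
spread). A label-independent metabolite is then not useless to a
multivariate metric — it carries dilution information that the
classifier can use as a reference to denoise informative metabolites.
Backward elimination consequently *retains* such "noise" metabolites
under realistic creatinine variation; the pure-noise elimination test
in the suite holds creatinine nearly constant to isolate the intended
construction.

Second, *diagonal relevance is a noisy ranker at study scale*. With 121
NAFLD subjects and 32 metabolites, the adaptive metric can spend weight
on multivariate chance structure; the middle of the true effect ranking
is recovered inconsistently (about 6 of the 10 simulated
discriminatory metabolites appear in the relevance top 10 at the
default effect sizes, against a chance level of 3.1, with the
top-ranked metabolite recovered almost always), while a 4-SD signal is
recovered essentially perfectly. This instability is the reason the
pipeline averages relevance over repeated splits and the reason
reduced panels are re-validated rather than trusted from a single
ranking.

## Problem sizes used by the test suite

The suite exercises the full pipeline at reduced settings chosen so the
statistical properties under test are stable: oracle-equivalence
instances up to n = 20, d = 6; training batteries of 20 seeds on
two-class cohorts of 100 subjects per class with 6 repeated splits;
backward elimination from 32 to 10 metabolites over 3 seeds with 5
splits per size. The bundled acceptance script
(`scripts/acceptance.R`) validates the default 275-subject cohort with
50 splits per contrast and a 10-split elimination trajectory.

## Known limitations

- One global relevance matrix (no localised or kernelised variants) and
  binary ROC evaluation only, matching the analysis design this
  package implements.
- Relevance-based rankings on cohorts of a few hundred subjects are
  stable only in their top ranks; treat mid-table orderings as noisy.
- The generator's class-conditional independence of metabolites (given
  creatinine) understates the redundancy of real steroid pathways;
  real-data relevance patterns will be flatter.
- Training hyperparameters are honest defaults, not tuned replicas of
  any particular study's (non-public) settings.
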