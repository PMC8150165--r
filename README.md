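# steroidstage

Non-invasive staging of non-alcoholic fatty liver disease (NAFLD)
fibrosis from the urinary steroid metabolome. The liver is the main
site of steroid hormone metabolism — 11β-HSD1 regenerates cortisol from
cortisone, the A-ring reductases inactivate it to tetrahydro-metabolites
excreted in urine — so a 32-metabolite GC-MS urinary steroid profile is
a functional readout of liver state. This package is for researchers
developing or benchmarking such biomarker panels: it implements the full
analysis pipeline from raw spot-urine concentrations to validated ROC
curves and reduced diagnostic panels, plus a synthetic cohort generator
that emulates a biopsy-staged case-control study so the entire pipeline
can be exercised and tested without patient data.

## What it computes

At its core is a from-scratch **Generalised Matrix Learning Vector
Quantisation (GMLVQ)** classifier: one prototype steroid profile per
disease stage, compared to a subject's profile through an adaptive
quadratic metric

> d(w, x) = (x − w)ᵀ Λ (x − w),  Λ = ΩᵀΩ,  trace(Λ) = 1,

where Ω is learned jointly with the prototypes by gradient descent on
the relative-distance cost Σ φ(μ), μ = (d_J − d_K)/(d_J + d_K). The
diagonal of the relevance matrix Λ ranks metabolites by their importance
to the classification, which drives sequential backward elimination to a
compact panel (e.g. 10 steroids). Binary contrasts (early F0-F2 vs
advanced F3-F4 fibrosis, controls vs disease, NAFLD vs alcohol-related
cirrhosis) are evaluated by repeated stratified train/test splits with
leakage-free preprocessing (creatinine correction, floored log10,
train-only z-scoring), trapezoidal ROC/AUC equal to tie-corrected
concordance, and percentile confidence intervals. Serum comparator
scores (APRI, FIB-4, AST/ALT, NAFLD fibrosis score, BARD) and
glucocorticoid enzyme-activity ratios (11β-HSD1, A-ring reductase,
total cortisol metabolites) are included, as are Kruskal-Wallis/Dunn
group comparisons.

## Worked example

```r
library(steroidstage)

cohort <- generate_cohort(cohort_spec(seed = 42))   # 275 synthetic subjects
report <- repeated_split_validation(cohort, "F0,F1,F2:F3,F4",
                                    n_splits = 25, test_fraction = 0.2,
                                    seed = 7, covariates = c("age", "bmi"))
report
#> Validation report [F0,F1,F2:F3,F4]: mean AUC 0.988 (95% CI 0.942-1.000), 25 splits
#>   top relevances: age_years=0.167, pregnenetriol=0.101, 5a_tetrahydro_11_dehydrocorticosterone=0.097, androstenedione=0.084, bmi_kg_m2=0.075

comparator_roc(cohort, "F0,F1,F2:F3,F4", "fib4")$auc
#> [1] 0.792

ratios <- compute_ratios(cohort_steroid_matrix(cohort))
grp <- ifelse(cohort$stage == "control", "control",
       ifelse(cohort$stage %in% c("F0","F1","F2"), "F0-2",
       ifelse(cohort$stage %in% c("F3","F4"), "F3-4", NA)))
k <- !is.na(grp)
group_compare(log10(ratios$hsd11b1_activity[k]), grp[k])
#> Kruskal-Wallis H = 32.74, p = 7.8e-08
#>   control vs F0-2  adjusted p = 1.00      (not significant)
#>   control vs F3-4  adjusted p = 8.3e-08   (significant)
#>   F0-2    vs F3-4  adjusted p = 9.2e-04   (significant)
```

Read: on this simulated cohort the steroid + age/BMI model separates
early from advanced fibrosis with a mean held-out AUC of 0.99
(steroids alone: ≈0.92 across seeds), clearly above FIB-4's 0.79, and
11β-HSD1 activity is elevated in advanced fibrosis but not early
disease — the data-generating pattern the simulator encodes.

Panel reduction and ranking:

```r
traj <- backward_eliminate(cohort, "F0,F1,F2:F3,F4", stop_at = 10,
                           n_splits = 10, seed = 11)
traj$steps          # AUC at every panel size from 32 down to 10
traj$final_panel    # the 10 retained steroids
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/steroidstage.R simulate --seed 1 --out runs/sim
Rscript inst/cli/steroidstage.R stage --input runs/sim/cohort.csv \
    --contrast F0,F1,F2:F3,F4 --covariates age,bmi --reduce-to 10 \
    --seed 1 --out runs/stage
Rscript inst/cli/steroidstage.R scores --input runs/sim/cohort.csv --out runs/scores
```

Every run writes a manifest (config, seed, version, config hash)
sufficient to reproduce it exactly.

## Package layout

- `R/cohort.R` — synthetic cohort specification and generator
- `R/preprocess.R` — creatinine correction, log10 flooring, z-scoring,
  enzyme ratios, covariate augmentation
- `R/scores.R` — serum comparator scores
- `R/gmlvq.R` — the GMLVQ classifier (distances, cost, gradients,
  training, relevances, 2-D projection, JSON serialisation)
- `R/evaluate.R` — ROC/AUC, repeated-split validation, group tests
- `R/panel.R` — relevance ranking and backward elimination
- `R/pipeline.R`, `inst/cli/steroidstage.R` — orchestration and CLI
- `vignettes/steroid-staging-methods.Rmd` — the model, its assumptions,
  numerical choices, what the simulator does and does not emulate
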