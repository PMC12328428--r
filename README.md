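# seroclust

Discriminative T cell cluster discovery from mass-cytometry compositions.

Rheumatoid arthritis splits into seropositive (SP-RA: ACPA and/or RF
positive) and seronegative (SN-RA) disease, with different prognosis and
treatment behavior. Mass cytometry (CyTOF) profiles tens of markers on
hundreds of thousands of T cells per cohort; after clustering, each subject
becomes a *composition* over T cell clusters (TCLs), and the scientific
question is which clusters discriminate SP-RA from SN-RA once clinical
background covariates (age, sex, symptom duration, NSAID use, DAS28-CRP)
are adjusted for.

`seroclust` implements that workflow end to end, for analysts working with
CyTOF cluster-abundance data at small clinical sample sizes:

1. **Clustering** — batch self-organizing map over pooled arcsinh-transformed
   CD3+ events, hierarchical metaclustering of the codebook to `K` clusters
   (e.g. 44 TCLs, or 12 activated-cell clusters after CD38+/HLA-DR+ gating),
   per-subject cluster counts and fractions.
2. **Compositional statistics** — centered log-ratio (CLR) transform
   (clr_k = log x_k − mean_j log x_j), Mann–Whitney tests (exact for the
   17-vs-16 cohort scale), IPW-weighted Mann–Whitney with a permutation null, weighted
   medians, Fisher exact and Kruskal–Wallis for clinical tables, Spearman
   correlation matrices — with Benjamini–Hochberg FDR applied within
   declared feature families.
3. **Causal weighting** — ridge-stabilized logistic propensity model for
   serostatus, stabilized/truncated inverse-probability weights, balance
   diagnostics (standardized mean differences).
4. **Selection** — the core estimator `dtcl_select()`: adaptive-LASSO
   weighted logistic regression (stage-1 ridge initial fit, penalty factors
   1/|β̂|^γ, coordinate descent over a 100-point λ grid, λ by stratified
   inner CV) refit inside every leave-one-out fold with fold-specific IPW;
   clusters selected in **strictly more than 50%** of folds are
   discriminative T cell clusters (D-TCLs).
5. **Validation** — bootstrap SVM (stratified 70/30 splits, RBF kernel,
   cost/gamma grid search by inner CV) with a seven-metric suite and mean
   ROC, a label-permutation test on the mean bootstrap AUC at fixed
   hyperparameters, and elastic-net / random-forest / gradient-boosting
   cross-checks.

Because patient-level CyTOF data of this kind are rarely shareable, the
package ships a synthetic cohort generator (`cohort_config()`,
`simulate_composition()`, `simulate_cells()`) built around a reference cohort
design — 17 healthy controls, 17 SN-RA, 16 SP-RA, 25 markers, 44 clusters,
planted cluster-abundance effects, covariates that genuinely confound the
serostatus label — so the entire pipeline is testable without any download.
See the methods vignette (`vignettes/methods.Rmd`) for the model, parameter
defaults and their rationale, and known limitations.

## Worked example

```r
library(seroclust)

# a synthetic cohort at the default reference dimensions, with 6 planted effects
cfg <- cohort_config(seed = 11)
sim <- simulate_composition(cfg)
dim(sim$composition$counts)
#> [1] 50 44

# LOOCV adaptive-LASSO stability selection with per-fold IPW
sel <- dtcl_select(sim$composition, sim$covariates, seed = 11)
sel
#> LOOCV adaptive-LASSO stability selection (33 folds)
#>   LOOCV accuracy: 81.8%
#>   D-TCLs (selection frequency > 50%): TCL02, TCL07, TCL35
sprintf("TCL%02d", sim$truth$discriminative_set)  # the planted truth
#> [1] "TCL02" "TCL07" "TCL13" "TCL21" "TCL28" "TCL35"

# bootstrap SVM validation of the selected clusters
bs <- bootstrap_svm(sel$features[, sel$dtcl], sel$y, n_boot = 200,
                    cost_grid = 2^seq(-3, 9, 2), gamma_grid = 2^seq(-9, 1, 2),
                    seed = 11)
round(bs$summary["auc", ], 3)
#>   mean  ci_lo  ci_hi iqr_lo iqr_hi
#>  0.978  0.800  1.000  0.960  1.000

# permutation test at the modal hyperparameters of the observed run
modal <- attr(bs$hyperparameters, "modal")
permutation_test_auc(sel$features[, sel$dtcl], sel$y, n_perm = 200,
                     fixed_cost = modal[1], fixed_gamma = modal[2],
                     n_boot_inner = 50, seed = 12)
#> Permutation test on mean bootstrap AUC
#>   observed 0.989; permuted null 0.497 (range 0.249-0.788); p = 0.004975
```

Here the 33 leave-one-out folds classify held-out subjects with 81.8%
accuracy. The three D-TCLs are all genuinely planted clusters (a *subset*
of the six planted effects: with leave-one-out resampling the stable set is
the sparse sufficient support, not the full causal set — see the methods
vignette). The bootstrap SVM on those clusters reaches a mean AUC of 0.978,
and the permutation test puts that performance far outside the
shuffled-label null (p ≈ 0.005, the minimum attainable with 200
permutations being 1/201).

The full pipeline (simulate → cluster → CLR → select → validate) is
available as `run_pipeline(pipeline_config(...), out)` and writes every
stage artifact plus a reproducibility manifest as delimited text; FCS 3.0
event files can be read with `read_fcs()`.

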