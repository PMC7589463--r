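# rimcore

Tumour **rim**/**core** sub-volume radiomics with bootstrap-ensemble
survival risk modelling, in R.

Radiomic risk models for head-and-neck and other solid tumours are usually
built from features of the entire gross tumour volume (GTV). But tumours
are spatially organised — proliferation at the periphery, hypoxia and
necrosis in the centre — so the *rim* and the *core* of a lesion may carry
different prognostic information for a time-to-event endpoint such as
loco-regional control. `rimcore` implements the complete analysis:

* **Sub-volume geometry**: inward rim/core splits at 3 and 5 mm margins on
  the exact Euclidean distance transform, a 40% minimum-core floor for
  small tumours, outward rim extensions of 1/2/3/5 mm, and soft-tissue
  re-segmentation to [−150, 180] HU, all on 1 mm isotropic grids (cubic
  spline resampling included).
* **Feature extraction**: 1538 features per ROI — 18 intensity statistics,
  38 histogram/intensity-volume-histogram/peak features and 95 grey-level
  texture features (GLCM, GLRLM, GLSZM, GLDZM, NGTDM, NGLDM) on the base
  image and nine filtered images (8 stationary coiflet-1 wavelet
  combinations + 1 multi-scale Laplacian-of-Gaussian), plus 28
  morphological features. Hot paths run in C++ (Rcpp).
* **Risk modelling**: five bootstrap feature selectors (Spearman, MIM,
  MIFS, MRMR, RFVI) × six survival learners (Cox, boosted-tree Cox,
  componentwise-linear boosted Cox, boosted Weibull AFT, random survival
  forest, maximally-selected-rank forest), trained as ensembles over
  bootstrap resamples of an exploratory cohort with averaged risk scores
  and strict exploratory/validation separation.
* **Evaluation**: Harrell's C-index with percentile-bootstrap CIs,
  median-risk Kaplan–Meier stratification with log-rank tests, 20 cm³
  tumour-volume subgroups, and a paired sign-flip comparison of
  sub-volumes across the model-combination grid.
* **Synthetic cohorts**: a phantom generator that plants a *known*
  rim-localised texture signal with proportional-hazards Weibull outcomes,
  so the whole pipeline is testable without clinical data.

## Worked example

Generate a 60-patient synthetic cohort whose rim texture drives the
hazard, extract base-image features for the 5 mm rim and core, train a
Spearman + Cox ensemble on the exploratory cohort and evaluate it on the
held-out validation cohort:

```r
library(rimcore)
library(dplyr)

cohort <- generate_cohort(
  n = 60, outcomes = outcome_spec(beta = 2, seed = 2),
  volume_range_cm3 = c(5, 40), seed = 1
)
feats <- cohort_features(
  cohort, rois = c("rim5", "core5"),
  transforms = "base", families = "statistical"
)
outcomes <- cohort[, c("patient_id", "time_months", "event")]
cohorts  <- cohort[, c("patient_id", "cohort")]
explor   <- cohort$patient_id[cohort$cohort == "exploratory"]

fit_roi <- function(roi) {
  train_risk_model(
    filter(feats, roi == !!roi), outcomes, explor,
    selector = "spearman", learner = "cox",
    n_bootstrap_select = 25, n_bootstrap_train = 50,
    tune_budget = 0, seed = 11
  )
}
rim_fit  <- fit_roi("rim5")
core_fit <- fit_roi("core5")

evaluate_model(rim_fit,  filter(feats, roi == "rim5"),  outcomes, cohorts,
               n_boot = 200, seed = 3)
evaluate_model(core_fit, filter(feats, roi == "core5"), outcomes, cohorts,
               n_boot = 200, seed = 3)
```

which prints (abridged):

```
# rim5
  selector learner c_index_explor c_index_valid ci_lo ci_hi logrank_p
  spearman cox              0.822          0.75 0.584 0.914   0.00384
# core5
  selector learner c_index_explor c_index_valid ci_lo ci_hi logrank_p
  spearman cox              0.638          0.47 0.273  0.68     0.872
```

The rim-based model recovers the planted signal (validation C-index 0.75,
significant median-risk stratification), while the core-based model stays
at chance — the rim-versus-core contrast the package is built to measure.
`run_experiment()` chains the same steps over the full nine-ROI grid
(entire, rim/core at 3 and 5 mm, extended rims) and any subset of the 30
selector × learner combinations, and `autoplot()` methods draw the
Kaplan–Meier curves and per-ROI C-index distributions.

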