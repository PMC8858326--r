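# edemapredict

Malignant cerebral edema — life-threatening brain swelling after large
hemispheric stroke — develops in only ~3% of patients, but it kills unless
decompressive surgery happens *before* deterioration. Routine head CT at
baseline and ~24 hours carries early quantitative signatures of evolving
edema: displacement of cerebrospinal fluid (CSF), effacement of sulci on
the stroke side, and growing asymmetry of hemispheric CSF volumes.

`edemapredict` is an R package for studying, end to end and entirely on
synthetic data, whether those CT-derived CSF volumetrics plus serial
clinical data can predict malignant edema with clinically useful
precision. It provides:

* **Cohort simulation** (`generate_cohort()`): 598-subject cohorts with
  exactly 20 malignant-edema cases, feature marginals and within-group
  Gaussian-copula dependence calibrated to published case/control
  statistics (e.g. pooled r = 0.65 between the 24-h hemispheric CSF ratio
  and ΔCSF), missingness to exercise imputation.
* **Head-CT phantoms** (`generate_head_phantom()`, `apply_edema()`):
  procedural 3-D volumes — skull shell, parenchyma, ventricles, sulcal CSF
  rim — with exact ground truth, plus unilateral edema (sulcal effacement,
  ventricle compression, midline shift, hypodense lesion) applied to the
  label field.
* **CSF volumetrics** (`extract_volumetrics()`): cranial-cavity and CSF
  segmentation, midline delineation by reflective-symmetry registration of
  the skull, hemispheric splitting, and the three biomarkers:

  - intracranial reserve = CSF volume / cranial volume at baseline,
  - ΔCSF = 100 × (CSF₂₄ − CSF₀) / CSF₀ (negative = displacement),
  - hemispheric CSF ratio = affected / contralateral CSF volume.

* **Prediction models** (`nested_cv()`): L2 logistic regression (glmnet),
  a feed-forward network, and a two-timestep LSTM (both networks
  implemented in-package with hand-derived, finite-difference-verified
  gradients), trained under nested stratified 10-fold cross-validation
  with fold-internal imputation/standardization and class weighting.
* **Evaluation** (`pr_curve()`, `bootstrap_auprc_pvalue()`): average
  precision as the primary summary (step integration, no optimistic PR
  interpolation), AUROC, Brier, three operating-point policies, and a
  paired stratified bootstrap p-value for AUPRC differences.
* **Explanation** (`exact_shapley()`, `force_report()`): exact
  interventional Shapley values on the probability scale over the 11 named
  clinical/imaging variables (timestep slots fused per variable for the
  recurrent model), with global importance summaries and per-subject
  force-style reports.

## Worked example

```r
library(edemapredict)

# a synthetic cohort with the designed 20/598 prevalence
tab <- generate_cohort(default_cohort_config(seed = 5L))
table(tab$outcome)
#>   0   1
#> 578  20

# cross-validated regression on the 11 automated variables
cv <- nested_cv(tab, model_spec("logistic"), variable_sets()$automated,
                seed = 5)
pr_curve(cv$label, cv$prob)$auprc
#> [1] 0.8790014

# paired baseline / follow-up phantom with moderate unilateral edema
ph <- generate_head_phantom(phantom_spec(seed = 7L))
fu <- apply_edema(ph$ct, ph$truth,
                  edema_spec("left", effacement = 0.5, compression = 0.3,
                             shift_mm = 5, lesion_ml = 40))
extract_volumetrics(ph$ct, fu$ct, lesion_side = "left")[
  , c("intracranial_reserve", "csf_ratio_24h", "delta_csf")]
#>   intracranial_reserve csf_ratio_24h delta_csf
#> 1            0.1077909     0.6714432 -29.15401
```

The extracted numbers read as: this phantom "patient" started with 10.8%
of the cranial volume as CSF, lost ~29% of total CSF by follow-up, and
retains only ~0.67 of the contralateral CSF volume on the stroke side —
the signature of evolving hemispheric edema (simulated ground truth for
this pair: ratio 0.665, ΔCSF −26.9%).

`run_pipeline(run_config(...))` chains the stages (simulate → train →
evaluate → explain) into a run directory with CSV/JSON artifacts and a
manifest of seeds and checksums; `predict_single()` is the
clinician-facing path from one scan pair plus clinical values to a
probability and a Shapley force report.

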