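# glioquant

Pre-contrast quantitative MRI analysis of treated gliomas.

After surgery and radiotherapy, glioma patients are followed with repeated
MRI. Whether residual abnormal tissue enhances after gadolinium injection is
a key clinical question, but contrast agent is costly and not always
tolerated. Fast multi-parametric sequences deliver quantitative T1, T2 and
proton-density (PD) maps of the whole brain in minutes, *before* any
contrast is given. `glioquant` asks how much of the diagnostic signal is
already present in those pre-contrast maps:

* Can voxels of abnormal tissue be told apart from normal white matter by
  their quantitative values alone?
* Can the enhancing region be recognized without injecting contrast?
* Can patients whose lesions will enhance be predicted from first-order
  statistics of the pre-contrast maps?

## What it computes

For each patient the package takes three coregistered quantitative maps
(T1, T2 in ms; PD in percent units) and three binary masks (T2
hyperintensity **T2h**, T1w enhancement **T1e**, white matter **WM**) in
NIfTI, and derives

* **ABN** = T2h ∪ T1e, the abnormal-tissue region,
* **PER**, a 1-cm perilesional shell around ABN, computed in world
  millimetres (so anisotropic voxels are handled correctly), and
* **nWM** = WM \ (ABN ∪ PER), normal-appearing white matter.

Inside each ROI it characterizes each map with the first-order statistics
mean, SD, Fisher skewness and Pearson kurtosis, and compares ROIs across
patients with exact Wilcoxon signed-rank tests (full-enumeration p-values
up to n = 20 pairs, average ranks under ties).

Voxel-wise classification uses composite metrics
`normT1T2 = √(T1² + T2²)` and `normlog = √(ln²T1 + ln²T2)` (plus
PD-augmented variants). For each of three questions — ABN vs nWM, T1e vs
the rest, T1e vs T2h — it pools voxels across patients, builds the ROC
curve, and picks the operating threshold maximizing Youden's index
J = sensitivity + specificity − 1; the threshold is then re-applied per
patient (rule: value > threshold inside the white-matter mask) and scored
against the reference masks.

Patient-level enhancement prediction runs leave-pair-out cross-validation:
for every (enhancing, non-enhancing) pair, an ROC is fitted on the
remaining patients' feature values, its Youden threshold classifies the
held-out pair, and AUCs are averaged over all folds (7 × 7 = 49 folds for
the default cohort design).

Because clinical cohorts cannot be redistributed, the package ships a
synthetic cohort generator: ellipsoidal white matter, lesion and enhancing
core, with per-ROI voxel values drawn from shifted lognormal distributions
whose mean, SD and skewness match published per-ROI statistics of a
14-patient treated-glioma cohort. All pipeline stages are exercised and
tested end-to-end on that generator.

## Worked example

```r
library(glioquant)

cohort <- generate_cohort(cohort_config(seed = 1))   # 7 + 7 patients

# Question 1: abnormal tissue vs normal white matter, log-norm metric
roc <- run_question(cohort, "abn_vs_nwm", "normlog")
print(roc)
#> <roc_result> AUC=0.9349  Youden: thr=8.418 sens=0.939 spec=0.817 (J=0.756)
#>   n+=6824 n-=168931, 175756 thresholds

# Cohort-level T1 means per ROI (mean over patients ± t-based 95% CI)
sm <- summarize_cohort(cohort_roi_stats(cohort, maps = "t1"))
subset(sm, statistic == "mean")
#>    map roi statistic     mean ci_halfwidth n_patients
#> 1   t1 nwm      mean  994.414      1.14120         14
#> 5   t1 per      mean 1059.189      2.83037         14
#> 9   t1 t2h      mean 1356.595      3.22225         14
#> 13  t1 t1e      mean 1743.919     43.88123          7

# Is lesion T1 higher than normal white matter across patients?
compare_rois(cohort_roi_stats(cohort, maps = "t1"), "t2h", "nwm",
             "t1", "mean")
#> <paired_test> W=105  p=0.0001221  n=14  (exact)

# Leave-pair-out prediction of enhancement from pre-contrast T1 kurtosis
feat <- build_feature_table(cohort)
leave_pair_out_cv(feat, "t1_kurtosis")
#> <cv_summary> t1_kurtosis: AUC 0.592 (0.072), sens 86% spec 43% acc 64% over 49 folds
```

The ROC separates abnormal from normal voxels with AUC 0.93 and an
operating threshold of 8.42 on the log-norm scale; per-ROI T1 means
reproduce the configured ordering nWM < PER < T2h < T1e; and the exact
signed-rank test rejects equality of lesion and white-matter T1 at
p ≈ 1.2 × 10⁻⁴ (the smallest value attainable with 14 strictly positive
differences is 2/2¹⁴).

A thin command-line wrapper is included:

```sh
Rscript inst/cli/glioquant.R simulate --out cohort/ --seed 7
Rscript inst/cli/glioquant.R analyze --manifest cohort/manifest.yaml --out report/
```

`analyze` writes the ROI summary and p-value tables, per-question ROC
curves, mask-agreement scores, the cross-validation grid and occurrence
table as CSV, plus a machine-readable `summary.json`.

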