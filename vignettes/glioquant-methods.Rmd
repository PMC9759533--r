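---
title: "Methods: pre-contrast quantitative MRI analysis of treated gliomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-contrast quantitative MRI analysis of treated gliomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioquant)
```

`glioquant` analyzes pre-contrast quantitative T1/T2/PD maps of treated
glioma patients. This vignette documents the model behind each stage, the
parameters that matter, the numerical conventions, and what the synthetic
cohort generator does and does not emulate.

## ROI model

Each patient contributes three coregistered quantitative volumes and three
raw binary masks. The package assumes coregistration has already happened:
all six volumes must share one grid and one voxel-to-world affine (absolute
tolerance `1e-4` per affine entry, which absorbs the float noise left by
linear resampling). Masks arriving from resampling pipelines may contain
interpolation residue, so they are binarized at `> 0.5`. Voxel indices are
0-based in the affine convention; world units are millimetres.

Three ROIs are derived from the raw masks:

* `abn = t2h | t1e` — the union of non-enhancing hyperintensity and the
  enhancing region. Treatment effects and tumor cannot be separated on
  conventional images, so they are analyzed as one abnormal compartment.
* `per` — every voxel whose centre lies within `radius_mm` (default 10 mm)
  of an ABN voxel centre, minus ABN. The shell is computed in **world
  units**: clinical quantitative maps often have strongly anisotropic
  voxels (e.g. 0.875 × 0.875 × 5 mm), and a "1 cm margin" is a physical
  distance, not a voxel count. Ball membership is closed
  (distance ≤ radius) so the convention is testable. Implementation is an
  FFT convolution with a ball-shaped structuring element, which is exactly
  equivalent to thresholding the voxel-centre Euclidean distance transform;
  the test suite verifies this against brute-force distance minimization.
  PER is not clipped to the brain or WM mask by default; it exists to
  absorb possibly infiltrated tissue that would otherwise contaminate
  "normal" white matter.
* `nwm = wm & !abn & !per` — normal-appearing white matter.

## First-order statistics

Within an ROI, each map is summarized by four statistics: arithmetic mean,
sample SD (n−1 denominator), Fisher skewness `g1 = m3 / m2^1.5` and
**Pearson (non-excess) kurtosis** `m4 / m2^2`, central moments with n
denominators. Two conventions had to be fixed where common software
disagrees: unbiased small-sample corrections are *not* applied to g1 and
kurtosis, and kurtosis is reported on the scale where a normal distribution
scores 3. Constant ROIs (m2 = 0) and ROIs with fewer than three voxels get
`NA` skewness/kurtosis with an explicit `defined = FALSE` flag rather than
a silent NaN.

Cohort-level tables report, per (ROI, map, statistic), the mean across
patients and a t-based 95 % confidence half-width
`qt(0.975, n-1) * SD / sqrt(n)`. With 7–14 patients a normal-quantile CI
would be anticonservative; the t quantile is the defensible default.
Patients lacking an ROI (no enhancement ⇒ no T1e) are excluded from that
ROI's cells.

## Paired comparisons

ROI-vs-ROI differences across patients use the Wilcoxon signed-rank test,
implemented in-package because the analysis needs exact two-sided p-values
*with* average ranks under ties — a combination base R's `wilcox.test`
does not provide (it falls back to a normal approximation whenever ties or
zeros appear). Zero differences are dropped; |differences| are ranked with
average ranks; the exact null distribution of W is computed by convolving
the per-rank masses (identical to enumerating all 2^n sign vectors, and
the suite checks that equivalence up to n = 14). Above `exact_limit = 20`
pairs a tie-corrected normal approximation without continuity correction
takes over. Two-sided p = min(1, 2 · min(P(W ≤ w), P(W ≥ w))).

Comparing the *enhancing* and *non-enhancing* patient groups with a paired
test requires a pairing that the data do not define. With equal group
sizes the package pairs patients by index order within each group, and
always reports an unpaired rank-sum p-value alongside as a cross-check;
with unequal groups it falls back to the rank-sum test with a warning.
The imposed pairing is an assumption, and both numbers are surfaced so a
reader can judge its effect.

## Voxel-wise classification

Composite metrics combine the maps voxel-by-voxel: `normT1T2 =
√(T1² + T2²)` and `normlog = √(ln²T1 + ln²T2)` with the **natural**
logarithm, plus PD-augmented three-component variants. Units are
deliberately mixed inside the norms (ms with ms, ms with percent), exactly
as the metrics are defined; no standardization is applied. The natural-log
choice is anchored by scale: at typical white-matter values
(T1 ≈ 993 ms, T2 ≈ 92 ms) `normlog` evaluates to ≈ 8.25 and at lesion
values (≈ 1354/152 ms) to ≈ 8.79, so a decision threshold in the 8.4
range sits between compartments; a base-10 logarithm would place the whole
scale near 4.

ROC curves are built from voxels pooled across patients (one cohort-level
curve per question). Candidate thresholds are midpoints between
consecutive distinct pooled values plus ∓∞ sentinels, so the strict
classification rule `value > threshold` is unambiguous and independent of
sample ordering. The AUC is the trapezoidal integral over
(1 − specificity, sensitivity), which equals tie-corrected pairwise
concordance P(pos > neg) + ½ P(pos = neg); the test suite asserts that
identity against a brute-force oracle, against `pROC`, and against the
closed form Φ(Δ/σ√2) for Gaussian classes. The Youden point maximizes
J = sensitivity + specificity − 1; ties are broken toward the **lower**
threshold (favouring sensitivity, fixed for reproducibility).

Three questions are posed: `abn_vs_nwm` (the perilesional shell is
excluded, since it may hide infiltrated tissue in normal-looking voxels),
`t1e_vs_rest` (negatives default to T2h + PER + nWM; the composition is an
argument because the narrower T2h + nWM variant is also defensible), and
`t1e_vs_t2h` (within ABN only). Learned thresholds are re-applied per
patient inside the white-matter mask (nWM ∪ PER ∪ ABN), and the predicted
masks are scored against the reference segmentation: sensitivity over the
reference voxels, specificity and accuracy over the whole evaluation mask,
in percent.

## Enhancement prediction

Patient-level features are the 4 statistics × 4 metrics (T1, T2, normT1T2,
normlog) of ABN voxels — 16 pre-contrast numbers per patient. Validation
is leave-pair-out: every (enhancing, non-enhancing) pair is held out once,
the ROC is fitted on the remaining patients, and the training Youden
threshold classifies both held-out patients with the strict high-feature ⇒
enhancing rule (the direction is fixed a priori because all group means
move upward with enhancement; an automatic per-fold flip would leak
information). With 7 + 7 patients this gives 49 folds and each patient is
held out exactly 7 times. Sensitivity, specificity and accuracy are
**pooled** over all 98 held-out classifications rather than averaged per
fold — pooling matches the per-patient occurrence bookkeeping (how often
each patient was called enhancing) and avoids averaging ratios with tiny
denominators; both views are derivable from the reported occurrence table.

## Synthetic cohort generator

The generator exists so that every downstream stage can be exercised and
tested without patient data. Geometry: a white-matter ellipsoid filling
~84 % of the grid extent; one ellipsoidal lesion with radius drawn from
`lesion_radius_range` (default 8–12 mm) and mildly anisotropic semi-axes,
jittered in position; for enhancing patients an inner core ellipsoid whose
volume fraction of the lesion is drawn from `core_fraction_range` (default
0.2–0.4). The default grid is 48 × 48 × 24 voxels at 1.75 × 1.75 × 2.5 mm
— around 5.5 × 10⁴ voxels per volume, chosen to keep a full 14-patient
cohort generation plus analysis in a few seconds while leaving every ROI
with enough voxels for stable statistics.

Voxel values are i.i.d. within an ROI, drawn from a **shifted lognormal**.
That family is the smallest one that can match the three targets the study
conditions specify — mean, SD and (positive) skewness: with
`w = exp(σ²)`, skewness `(w+2)√(w−1)` determines w, the SD constraint
gives the shift `mean − sd/√(w−1)`, and the mean fixes μ. When no skewness
target is given, the shift is taken as configured and the first two
moments are matched by direct inversion. Kurtosis is left free — a
four-parameter family could pin it too, but no downstream stage depends on
matching it, and the fitted lognormal's analytic kurtosis is exposed via
`lognormal_params()` for sampling-error bounds. Default T1 and T2 targets
are the published per-ROI cohort statistics of a 14-patient treated-glioma
study, which order the means nWM < PER < T2h < T1e on both maps; PD
defaults are synthetic placeholders (T2h ≈ T1e, both above nWM/PER) since
the corresponding published table is supplementary and was not available
— they are configurable and drive no headline analysis.

Per-patient heterogeneity of the *distributions* (real patients differ
widely) is available as `mean_jitter`, a relative SD applied to each
spec's target mean per patient, but **defaults to 0** so that pooled
cohort moments equal the configured targets exactly and moment-recovery
tests are sharp. Reproducibility: each patient's substream seed is derived
deterministically from the cohort seed and patient index, so cohorts are
bit-identical across runs and platforms.

What the generator does *not* emulate: spatial texture within ROIs (all
downstream statistics are first-order, so i.i.d. values suffice),
partial-volume rims at mask edges and CSF boundaries (a known source of
false positives in real data), bias fields, estimator noise of the mapping
sequence, and realistic anatomy. Consequently, passing tests demonstrate
the correctness of the computational pipeline under the configured value
distributions — not the clinical performance of the thresholds on real
brains. Notably, because enhancing cores are drawn from a genuinely
higher-mean distribution, patient-level mean features separate the groups
perfectly in synthetic cohorts, which is *easier* than the real task; the
cross-validation machinery is therefore validated by its bookkeeping
invariants and degenerate-case behavior, not by reproducing clinical AUCs.

## Numerical choices and degenerate inputs

* Maps are processed as 64-bit doubles regardless of on-disk type; masks
  are written as uint8 so round trips are bit-exact.
* `normlog` at non-positive T1/T2 yields `NA` voxels with a warning and a
  count attribute; loading rejects patients with non-positive T1/T2 inside
  any raw mask outright.
* FFT dilation pads by the kernel half-width per axis, so circular
  wrap-around cannot occur; convolution outputs are integer counts, making
  the 0.5 detection threshold safe against round-off.
* An empty ABN produces an empty shell, not an error; an empty class in
  ROC construction, an empty ROI in statistics, and an all-zero difference
  vector in the signed-rank test are hard errors naming the condition.
* Lesions that cannot fit in the grid together with their 1-cm shell abort
  generation with a geometry error rather than silently truncating.

## Problem sizes

The shipped tests run the full pipeline on 14-patient cohorts with
32 × 32 × 16 and 48 × 48 × 24 grids (1.6 × 10⁴–5.5 × 10⁴ voxels per
volume), sampling checks at 1–2 × 10⁵ draws, exact-test enumeration up to
2¹⁴ sign vectors, and 100-instance ROC oracle sweeps at up to 200 values
per class; the whole suite completes in well under a minute, and
`scripts/acceptance.R` regenerates and analyzes the default cohort in a
few seconds.

## Known limitations

* The pooled ROC weights voxels, not patients; large lesions dominate.
  Patient-weighted pooling would be a reasonable alternative and the
  per-patient mask-agreement stage partially compensates.
* The index pairing imposed on the two patient groups is arbitrary; the
  rank-sum cross-check should always be consulted alongside.
* First-order statistics ignore all spatial context by construction;
  neighborhood-aware or learned classifiers are out of scope.
* PD defaults in the generator are placeholders, not published values.
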