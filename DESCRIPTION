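Package: glioquant
Title: Pre-Contrast Quantitative MRI Analysis of Treated Gliomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pre-contrast quantitative MRI (T1, T2 and
    proton-density maps) in treated glioma cohorts. Derives regions of interest
    from lesion masks (abnormal tissue, a 1-cm perilesional shell computed in
    world units, and normal-appearing white matter), characterizes map values
    inside each region with first-order histogram statistics (mean, SD,
    skewness, kurtosis), compares regions and patient groups with exact
    Wilcoxon signed-rank tests, classifies voxels as abnormal or enhancing via
    composite T1/T2 metrics with ROC curves and Youden-optimal thresholds, and
    predicts contrast enhancement at the patient level with leave-pair-out
    cross-validation. Includes a synthetic cohort generator that emulates the
    geometry and right-skewed value distributions of a 14-patient treated
    glioma study, so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
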