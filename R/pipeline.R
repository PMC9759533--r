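#' Write a cohort to disk as NIfTI files plus a YAML manifest
#'
#' One directory per patient containing the three maps and three raw masks;
#' a `manifest.yaml` at the top maps each patient id to its six file roles,
#' decoupling file naming from the loading code.
#'
#' @param cohort List of [patient_record()]s.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (rec in cohort) {
    pid <- rec$maps$patient_id
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    aff <- rec$maps$affine
    paths <- list(
      t1 = file.path(pdir, "t1.nii.gz"), t2 = file.path(pdir, "t2.nii.gz"),
      pd = file.path(pdir, "pd.nii.gz"),
      t2h = file.path(pdir, "mask_t2h.nii.gz"),
      t1e = file.path(pdir, "mask_t1e.nii.gz"),
      wm = file.path(pdir, "mask_wm.nii.gz"))
    save_map(rec$maps$t1, aff, paths$t1)
    save_map(rec$maps$t2, aff, paths$t2)
    save_map(rec$maps$pd, aff, paths$pd)
    save_mask(rec$rois$t2h, aff, paths$t2h)
    save_mask(rec$rois$t1e, aff, paths$t1e)
    save_mask(rec$rois$wm, aff, paths$wm)
    manifest[[pid]] <- lapply(paths, function(p)
      sub(paste0("^", dir, "/?"), "", p))
  }
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Read a cohort manifest
#'
#' @param path Path to a `manifest.yaml` written by [write_cohort()] (or
#'   hand-written in the same patient -> role -> path layout).
#' @return Named list of per-patient role-path lists; paths resolved
#'   relative to the manifest's directory.
#' @export
read_manifest <- function(path) {
  manifest <- yaml::read_yaml(path)
  base <- dirname(path)
  lapply(manifest, function(roles)
    lapply(roles, function(p)
      if (startsWith(p, "/")) p else file.path(base, p)))
}

#' Load a cohort from a manifest and derive its ROIs
#'
#' @param manifest Manifest path or the list returned by [read_manifest()].
#' @param radius_mm Perilesional shell radius (mm).
#' @param affine_tol Affine agreement tolerance passed to [load_patient()].
#' @return List of derived [patient_record()]s.
#' @export
load_cohort <- function(manifest, radius_mm = 10, affine_tol = 1e-4) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lapply(names(manifest), function(pid) {
    r <- manifest[[pid]]
    rec <- load_patient(r$t1, r$t2, r$pd, r$t2h, r$t1e, r$wm,
                        patient_id = pid, affine_tol = affine_tol)
    derive_rois(rec, radius_mm = radius_mm)
  })
}

#' Run the full analysis pipeline on a cohort
#'
#' Orchestrates all stages: per-patient and cohort-level ROI statistics with
#' ROI-vs-ROI signed-rank p-values, the three voxel-wise classification
#' questions over the requested metrics with Youden operating points,
#' optional threshold re-application producing predicted abnormality and
#' enhancement masks scored against the reference masks, the group
#' comparison of abnormal-tissue features, and leave-pair-out
#' cross-validated enhancement prediction. Writes CSV/JSON reports to
#' `out_dir` when given.
#'
#' @param cohort List of derived [patient_record()]s.
#' @param out_dir Optional output directory for the report bundle.
#' @param metrics Metrics used for the voxel-wise questions.
#' @param questions Classification questions to run.
#' @param thresholds Optional named list of fixed thresholds, e.g.
#'   `list(abn = list(metric = "normlog", value = 8.44), t1e = list(metric =
#'   "normT1T2", value = 1344))`; when `NULL`, the cohort's own Youden
#'   thresholds for `abn_vs_nwm` / `t1e_vs_rest` are re-applied.
#' @param write_masks Write predicted masks as NIfTI (requires `out_dir`).
#' @return List with `roi_summary`, `roi_pvalues`, `roc`, `mask_agreement`,
#'   `group_comparison`, `cv`, `occurrence`, `provenance`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         metrics = c("t1", "t2", "normT1T2", "normlog"),
                         questions = c("abn_vs_nwm", "t1e_vs_rest",
                                       "t1e_vs_t2h"),
                         thresholds = NULL, write_masks = FALSE) {
  if (length(cohort) == 0) stop("empty cohort")
  any_enh <- any(vapply(cohort, `[[`, logical(1), "has_enhancement"))

  stats_df <- cohort_roi_stats(cohort)
  roi_summary <- summarize_cohort(stats_df)
  roi_pvalues <- roi_pvalue_table(stats_df)

  roc <- list()
  for (q in questions) {
    if (q != "abn_vs_nwm" && !any_enh) {
      message("notice: no enhancing patients; question '", q, "' skipped")
      next
    }
    for (mt in metrics)
      roc[[paste(q, mt, sep = ".")]] <- run_question(cohort, q, mt)
  }

  # threshold re-application: one global threshold per question, applied to
  # each patient inside the white-matter mask (nWM + PER + ABN)
  if (is.null(thresholds)) {
    thresholds <- list()
    if (!is.null(roc[["abn_vs_nwm.normlog"]]))
      thresholds$abn <- list(metric = "normlog",
                             value = roc[["abn_vs_nwm.normlog"]]$youden$threshold)
    if (!is.null(roc[["t1e_vs_rest.normT1T2"]]))
      thresholds$t1e <- list(metric = "normT1T2",
                             value = roc[["t1e_vs_rest.normT1T2"]]$youden$threshold)
  }
  agreement <- list()
  for (tname in names(thresholds)) {
    th <- thresholds[[tname]]
    truth_roi <- if (tname == "abn") "abn" else "t1e"
    rows <- list()
    for (rec in cohort) {
      if (truth_roi == "t1e" && !rec$has_enhancement) next
      evalmask <- rec$rois$nwm | rec$rois$per | rec$rois$abn
      vol <- suppressWarnings(compute_metric(rec$maps, th$metric))
      pred <- apply_threshold(vol, th$value, evalmask)
      ag <- evaluate_masks(pred, rec$rois[[truth_roi]], evalmask)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = rec$maps$patient_id, target = tname,
        metric = th$metric, threshold = th$value,
        sensitivity = ag$sensitivity, specificity = ag$specificity,
        accuracy = ag$accuracy)
      if (write_masks && !is.null(out_dir)) {
        mdir <- file.path(out_dir, "predicted_masks")
        dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
        save_mask(pred, rec$maps$affine,
                  file.path(mdir, paste0(rec$maps$patient_id, "_",
                                         tname, "_pred.nii.gz")))
      }
    }
    agreement[[tname]] <- do.call(rbind, rows)
  }

  group_cmp <- NULL; cv_sums <- NULL; prediction <- NULL; occurrence <- NULL
  if (any_enh && !all(vapply(cohort, `[[`, logical(1), "has_enhancement"))) {
    feat <- build_feature_table(cohort)
    fcols <- setdiff(names(feat), c("patient_id", "has_enhancement"))
    group_cmp <- lapply(fcols, function(fc) {
      res <- tryCatch(compare_groups(feat[[fc]], feat$has_enhancement),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(feature = fc, p_value = res$p_value,
                 rank_sum_p = res$rank_sum_p, method = res$method)
    })
    group_cmp <- do.call(rbind, group_cmp)
    cv_sums <- lapply(fcols, function(fc) leave_pair_out_cv(feat, fc))
    names(cv_sums) <- fcols
    prediction <- summarize_prediction(cv_sums)
    best <- prediction$best_feature
    occurrence <- cv_sums[[best]]$occurrence
  } else {
    message("notice: cohort lacks one of the groups; ",
            "group comparison and cross-validation skipped")
  }

  provenance <- list(
    n_patients = length(cohort),
    n_enhancing = sum(vapply(cohort, `[[`, logical(1), "has_enhancement")),
    metrics = metrics, questions = questions,
    thresholds = thresholds,
    settings = list(mask_binarization = "> 0.5",
                    youden_ties = "lowest threshold",
                    classification_rule = "value > threshold",
                    log_base = "natural"),
    version = as.character(utils::packageVersion("glioquant")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  result <- list(roi_summary = roi_summary, roi_pvalues = roi_pvalues,
                 roc = roc, mask_agreement = agreement,
                 group_comparison = group_cmp, cv = cv_sums,
                 prediction = prediction, occurrence = occurrence,
                 provenance = provenance)
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  invisible(result)
}

# ROI-vs-ROI signed-rank p-value grid (layout of the study's T1/T2 tables)
roi_pvalue_table <- function(stats_df,
                             ref_rois = c("nwm", "t2h", "t1e")) {
  rows <- list()
  for (mp in unique(stats_df$map)) {
    for (roi in unique(stats_df$roi)) {
      for (ref in ref_rois) {
        if (ref == roi) next
        for (st in c("mean", "sd", "skewness", "kurtosis")) {
          p <- tryCatch(
            compare_rois(stats_df, roi, ref, mp, st)$p_value,
            error = function(e) NA_real_)
          rows[[length(rows) + 1L]] <- data.frame(
            map = mp, roi = roi, vs = ref, statistic = st, p_value = p)
        }
      }
    }
  }
  do.call(rbind, rows)
}

write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$roi_summary,
                   file.path(out_dir, "roi_summary.csv"), row.names = FALSE)
  utils::write.csv(result$roi_pvalues,
                   file.path(out_dir, "roi_pvalues.csv"), row.names = FALSE)
  for (nm in names(result$roc)) {
    r <- result$roc[[nm]]
    utils::write.csv(
      data.frame(threshold = r$thresholds, sensitivity = r$sensitivity,
                 specificity = r$specificity),
      file.path(out_dir, paste0("roc_", nm, ".csv")), row.names = FALSE)
  }
  for (nm in names(result$mask_agreement))
    utils::write.csv(result$mask_agreement[[nm]],
                     file.path(out_dir, paste0("mask_agreement_", nm, ".csv")),
                     row.names = FALSE)
  if (!is.null(result$group_comparison))
    utils::write.csv(result$group_comparison,
                     file.path(out_dir, "group_comparison.csv"),
                     row.names = FALSE)
  if (!is.null(result$prediction))
    utils::write.csv(result$prediction$table,
                     file.path(out_dir, "cv_prediction.csv"),
                     row.names = FALSE)
  if (!is.null(result$occurrence))
    utils::write.csv(result$occurrence,
                     file.path(out_dir, "cv_occurrence.csv"),
                     row.names = FALSE)
  summary <- list(
    provenance = result$provenance,
    auc = lapply(result$roc, `[[`, "auc"),
    youden = lapply(result$roc, `[[`, "youden"),
    best_feature = if (!is.null(result$prediction))
      result$prediction$best_feature)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
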