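#' Per-patient feature table from abnormal-tissue statistics
#'
#' For each patient, computes the four first-order statistics (mean, SD,
#' skewness, kurtosis) of each of the four voxel metrics (`t1`, `t2`,
#' `normT1T2`, `normlog`) inside the abnormal region, giving 16 pre-contrast
#' features per patient, plus the enhancement label.
#'
#' @param cohort List of derived [patient_record()]s, all with non-empty ABN.
#' @return Data frame: `patient_id`, `has_enhancement`, and columns named
#'   `<metric>_<statistic>`.
#' @export
build_feature_table <- function(cohort) {
  metrics <- c("t1", "t2", "normT1T2", "normlog")
  rows <- lapply(cohort, function(rec) {
    if (is.null(rec$rois$abn) || !any(rec$rois$abn))
      stop("empty ABN for patient '", rec$maps$patient_id, "'")
    row <- list(patient_id = rec$maps$patient_id,
                has_enhancement = rec$has_enhancement)
    for (mt in metrics) {
      vol <- suppressWarnings(compute_metric(rec$maps, mt))
      vals <- vol[rec$rois$abn]
      vals <- vals[is.finite(vals)]
      s <- compute_roi_stats(vals)
      row[[paste0(mt, "_mean")]] <- s$mean
      row[[paste0(mt, "_sd")]] <- s$sd
      row[[paste0(mt, "_skewness")]] <- s$skewness
      row[[paste0(mt, "_kurtosis")]] <- s$kurtosis
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

#' Leave-pair-out cross-validated prediction of enhancement
#'
#' For every (enhancing, non-enhancing) patient pair, an ROC is fitted on the
#' remaining patients' values of `feature`, its AUC recorded, and the
#' training Youden threshold applied to classify both held-out patients by
#' the strict rule feature > threshold (high feature = enhancing).
#' Sensitivity, specificity and accuracy are pooled over all held-out
#' classifications; per-patient occurrence counts of being called enhancing
#' are tallied.
#'
#' @param table Data frame from [build_feature_table()].
#' @param feature Feature column name, e.g. `"t1_kurtosis"`.
#' @return Object of class `cv_summary`: `feature`, `mean_auc`, `sd_auc`,
#'   `fold_aucs`, `sensitivity`, `specificity`, `accuracy` (percent),
#'   `n_folds`, and `occurrence` (data frame: patient, label, times held
#'   out, times classified enhancing).
#' @export
leave_pair_out_cv <- function(table, feature) {
  stopifnot(feature %in% names(table))
  v <- table[[feature]]
  lab <- table$has_enhancement
  if (any(!is.finite(v)))
    stop("feature '", feature, "' has non-finite values")
  pos_idx <- which(lab); neg_idx <- which(!lab)
  if (length(pos_idx) == 0 || length(neg_idx) == 0)
    stop("both classes must be non-empty")
  n_folds <- 0L
  aucs <- numeric(0)
  held <- integer(nrow(table)); called <- integer(nrow(table))
  correct_pos <- 0L; correct_neg <- 0L
  for (i in pos_idx) for (j in neg_idx) {
    train <- setdiff(seq_len(nrow(table)), c(i, j))
    tr_pos <- v[intersect(train, pos_idx)]
    tr_neg <- v[intersect(train, neg_idx)]
    if (length(tr_pos) == 0 || length(tr_neg) == 0) {
      warning("fold (", i, ",", j, ") skipped: empty training class")
      next
    }
    roc <- build_roc(tr_pos, tr_neg)
    n_folds <- n_folds + 1L
    aucs <- c(aucs, roc$auc)
    thr <- roc$youden$threshold
    for (h in c(i, j)) {
      held[h] <- held[h] + 1L
      hit <- v[h] > thr
      if (hit) called[h] <- called[h] + 1L
      if (lab[h] && hit) correct_pos <- correct_pos + 1L
      if (!lab[h] && !hit) correct_neg <- correct_neg + 1L
    }
  }
  n_pos_slots <- sum(held[pos_idx]); n_neg_slots <- sum(held[neg_idx])
  structure(list(
    feature = feature,
    mean_auc = mean(aucs), sd_auc = stats::sd(aucs), fold_aucs = aucs,
    sensitivity = 100 * correct_pos / n_pos_slots,
    specificity = 100 * correct_neg / n_neg_slots,
    accuracy = 100 * (correct_pos + correct_neg) /
      (n_pos_slots + n_neg_slots),
    n_folds = n_folds,
    occurrence = data.frame(patient_id = table$patient_id,
                            has_enhancement = lab,
                            times_held_out = held,
                            times_classified_enhancing = called)),
    class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf(
    "<cv_summary> %s: AUC %.3f (%.3f), sens %.0f%% spec %.0f%% acc %.0f%% over %d folds\n",
    x$feature, x$mean_auc, x$sd_auc, x$sensitivity, x$specificity,
    x$accuracy, x$n_folds))
  invisible(x)
}

#' Summarize cross-validated prediction over features
#'
#' Emits one row per feature (mean/SD of fold AUCs, pooled sensitivity,
#' specificity, accuracy) and flags the best feature by mean AUC, ties
#' broken by accuracy.
#'
#' @param cv_summaries List of `cv_summary` objects.
#' @return List with `table` (data frame) and `best_feature`.
#' @export
summarize_prediction <- function(cv_summaries) {
  if (length(cv_summaries) == 0) stop("at least one feature required")
  tab <- do.call(rbind, lapply(cv_summaries, function(s)
    data.frame(feature = s$feature, mean_auc = s$mean_auc,
               sd_auc = s$sd_auc, sensitivity = s$sensitivity,
               specificity = s$specificity, accuracy = s$accuracy)))
  ord <- order(-tab$mean_auc, -tab$accuracy)
  tab$best <- seq_len(nrow(tab)) == ord[1]
  list(table = tab, best_feature = tab$feature[ord[1]])
}
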