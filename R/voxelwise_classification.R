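#' Composite voxel-wise metric identifiers
#'
#' The closed vocabulary of voxel metrics: raw `t1` and `t2` (ms), the
#' Euclidean norm `normT1T2 = sqrt(T1^2 + T2^2)`, the log-norm
#' `normlog = sqrt(ln(T1)^2 + ln(T2)^2)` (natural logarithm), and the
#' PD-augmented variants `normT1T2PD` and `normlogT1T2PD` which append PD
#' (or ln PD) as a third component. Units are mixed inside the norms (ms with
#' ms, ms with percent for the PD variants) by design; no standardization is
#' applied.
#'
#' @export
metric_ids <- c("t1", "t2", "normT1T2", "normlog", "normT1T2PD",
                "normlogT1T2PD")

#' Compute a composite voxel metric volume
#'
#' @param maps A [quant_map_set()].
#' @param metric One of [metric_ids].
#' @return Numeric 3-D array. Voxels with non-positive T1/T2 (or PD for the
#'   PD log variant) under a logarithmic metric are set to `NA`; their count
#'   is reported via a warning and the `"n_masked"` attribute.
#' @export
compute_metric <- function(maps, metric = metric_ids) {
  metric <- match.arg(metric)
  t1 <- maps$t1; t2 <- maps$t2; pd <- maps$pd
  n_masked <- 0L
  vol <- switch(metric,
    t1 = t1,
    t2 = t2,
    normT1T2 = sqrt(t1^2 + t2^2),
    normT1T2PD = sqrt(t1^2 + t2^2 + pd^2),
    normlog = {
      bad <- !(t1 > 0 & t2 > 0)
      n_masked <- sum(bad)
      lt1 <- log(pmax(t1, .Machine$double.xmin))
      lt2 <- log(pmax(t2, .Machine$double.xmin))
      out <- sqrt(lt1^2 + lt2^2)
      out[bad] <- NA_real_
      out
    },
    normlogT1T2PD = {
      bad <- !(t1 > 0 & t2 > 0 & pd > 0)
      n_masked <- sum(bad)
      lt1 <- log(pmax(t1, .Machine$double.xmin))
      lt2 <- log(pmax(t2, .Machine$double.xmin))
      lpd <- log(pmax(pd, .Machine$double.xmin))
      out <- sqrt(lt1^2 + lt2^2 + lpd^2)
      out[bad] <- NA_real_
      out
    })
  if (n_masked > 0)
    warning(n_masked, " voxel(s) with non-positive values masked out of '",
            metric, "'")
  attr(vol, "n_masked") <- n_masked
  vol
}

#' Build an ROC curve from pooled positive and negative values
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' pooled values, plus -Inf/+Inf sentinels; a voxel is called positive when
#' its value is strictly greater than the threshold. The AUC is the
#' trapezoidal integral over (1 - specificity, sensitivity), which equals
#' the tie-corrected pairwise concordance P(pos > neg) + 0.5 P(pos = neg).
#' The Youden-optimal point maximizes J = sensitivity + specificity - 1;
#' ties are broken toward the lower threshold.
#'
#' @param positive_values,negative_values Non-empty numeric vectors.
#' @return Object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `youden` (list with `threshold`, `sensitivity`,
#'   `specificity`, `j`), `n_positive`, `n_negative`.
#' @export
build_roc <- function(positive_values, negative_values) {
  pos <- as.numeric(positive_values); neg <- as.numeric(negative_values)
  pos <- pos[is.finite(pos)]; neg <- neg[is.finite(neg)]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must contain at least one finite value")
  v <- sort(unique(c(pos, neg)))
  k <- length(v)
  thr <- c(-Inf, if (k > 1) (v[-1] + v[-k]) / 2, Inf)
  # counts of values >= v[i], accumulated from the top
  pos_tab <- tabulate(findInterval(pos, v), nbins = k)
  neg_tab <- tabulate(findInterval(neg, v), nbins = k)
  pos_ge <- rev(cumsum(rev(pos_tab)))
  neg_ge <- rev(cumsum(rev(neg_tab)))
  # threshold i in 2..k leaves values >= v[i] positive; -Inf all, +Inf none
  sens <- c(1, pos_ge[-1] / length(pos), 0)
  fpr <- c(1, neg_ge[-1] / length(neg), 0)
  spec <- 1 - fpr
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
               (sens[-length(sens)] + sens[-1]) / 2)
  j <- sens + spec - 1
  best <- which.max(j)  # first maximum = lowest threshold
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc,
                 youden = list(threshold = thr[best],
                               sensitivity = sens[best],
                               specificity = spec[best], j = j[best]),
                 n_positive = length(pos), n_negative = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC=%.4f  Youden: thr=%.4g sens=%.3f spec=%.3f (J=%.3f)\n",
    x$auc, x$youden$threshold, x$youden$sensitivity, x$youden$specificity,
    x$youden$j))
  cat(sprintf("  n+=%d n-=%d, %d thresholds\n", x$n_positive, x$n_negative,
              length(x$thresholds)))
  invisible(x)
}

#' Pool voxels across a cohort for one classification question
#'
#' Questions: `abn_vs_nwm` (abnormal tissue vs normal-appearing white
#' matter; the perilesional shell is excluded), `t1e_vs_rest` (enhancing
#' voxels vs a configurable negative set, by default T2h + PER + nWM) and
#' `t1e_vs_t2h` (within the abnormal region only).
#'
#' @param cohort List of derived [patient_record()]s.
#' @param question One of `"abn_vs_nwm"`, `"t1e_vs_rest"`, `"t1e_vs_t2h"`.
#' @param metric One of [metric_ids].
#' @param rest_rois Negative-set ROIs for `t1e_vs_rest`.
#' @return List with `positive` and `negative` pooled value vectors.
#' @export
pool_question_values <- function(cohort, question = c("abn_vs_nwm",
                                                      "t1e_vs_rest",
                                                      "t1e_vs_t2h"),
                                 metric = metric_ids,
                                 rest_rois = c("t2h", "per", "nwm")) {
  question <- match.arg(question)
  metric <- match.arg(metric)
  pos <- list(); neg <- list()
  for (rec in cohort) {
    vol <- suppressWarnings(compute_metric(rec$maps, metric))
    r <- rec$rois
    if (question == "abn_vs_nwm") {
      pos[[length(pos) + 1L]] <- vol[r$abn]
      neg[[length(neg) + 1L]] <- vol[r$nwm]
    } else if (question == "t1e_vs_rest") {
      if (rec$has_enhancement) pos[[length(pos) + 1L]] <- vol[r$t1e]
      nm <- Reduce(`|`, r[rest_rois])
      neg[[length(neg) + 1L]] <- vol[nm & !r$t1e]
    } else {
      if (rec$has_enhancement) pos[[length(pos) + 1L]] <- vol[r$t1e]
      neg[[length(neg) + 1L]] <- vol[r$t2h & !r$t1e]
    }
  }
  list(positive = unlist(pos), negative = unlist(neg))
}

#' Run one classification question on a cohort
#'
#' Pools voxels across patients with [pool_question_values()] and builds the
#' cohort-level ROC.
#'
#' @inheritParams pool_question_values
#' @return A `roc_result`.
#' @export
run_question <- function(cohort, question = c("abn_vs_nwm", "t1e_vs_rest",
                                              "t1e_vs_t2h"),
                         metric = metric_ids,
                         rest_rois = c("t2h", "per", "nwm")) {
  question <- match.arg(question)
  vals <- pool_question_values(cohort, question, metric, rest_rois)
  if (question != "abn_vs_nwm" && length(vals$positive) == 0)
    stop("no enhancing voxels in the cohort: question '", question,
         "' is undefined")
  build_roc(vals$positive, vals$negative)
}

#' Apply a learned threshold to a metric volume
#'
#' Strict rule: value > threshold, restricted to the evaluation mask (by
#' convention the white-matter mask, i.e. nWM + PER + ABN).
#'
#' @param metric_volume Numeric 3-D array.
#' @param threshold Scalar threshold.
#' @param evaluation_mask Non-empty binary mask.
#' @return Logical mask of supra-threshold voxels inside the mask.
#' @export
apply_threshold <- function(metric_volume, threshold, evaluation_mask) {
  m <- as_mask(evaluation_mask)
  if (!any(m)) stop("evaluation_mask is empty")
  out <- !is.na(metric_volume) & metric_volume > threshold & m
  dim(out) <- dim(metric_volume)
  out
}

#' Agreement between a predicted and a reference mask
#'
#' Sensitivity = TP/(TP+FN) over the reference voxels inside the evaluation
#' mask; specificity = TN/(TN+FP) and accuracy over the whole evaluation
#' mask. All in percent. Components whose class is empty are `NA` with a
#' `defined` flag.
#'
#' @param predicted,truth Binary masks of one shape.
#' @param evaluation_mask Binary mask over which agreement is scored.
#' @return Object of class `mask_agreement`: `sensitivity`, `specificity`,
#'   `accuracy` (percent), `defined`, and the confusion counts.
#' @export
evaluate_masks <- function(predicted, truth, evaluation_mask) {
  p <- as_mask(predicted); t <- as_mask(truth); e <- as_mask(evaluation_mask)
  if (!identical(dim(p), dim(t)) || !identical(dim(p), dim(e)))
    stop("masks must share one shape")
  tp <- sum(p & t & e); fn <- sum(!p & t & e)
  fp <- sum(p & !t & e); tn <- sum(!p & !t & e)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- if (tp + fn + fp + tn > 0)
    100 * (tp + tn) / (tp + fn + fp + tn) else NA_real_
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 defined = c(sensitivity = tp + fn > 0,
                             specificity = tn + fp > 0),
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "mask_agreement")
}

#' @export
print.mask_agreement <- function(x, ...) {
  cat(sprintf("<mask_agreement> sens=%.2f%% spec=%.2f%% acc=%.2f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}
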