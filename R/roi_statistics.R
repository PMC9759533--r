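#' First-order statistics of map values inside an ROI
#'
#' Computes the four first-order histogram statistics used throughout the
#' pipeline: arithmetic mean, sample SD (n-1 denominator), Fisher skewness
#' g1 = m3 / m2^(3/2) and Pearson (non-excess) kurtosis m4 / m2^2, where the
#' central moments mk use n denominators. For constant input (m2 = 0) or
#' fewer than three voxels, skewness and kurtosis are returned as `NA` with
#' `defined = FALSE`.
#'
#' @param map_volume Numeric 3-D array, or a plain numeric vector of values.
#' @param roi_mask Logical/0-1 array of the same shape, or integer voxel
#'   indices; ignored when `map_volume` is already a vector.
#' @return Object of class `roi_stats`: `mean`, `sd`, `skewness`, `kurtosis`,
#'   `n_voxels`, `defined`.
#' @export
compute_roi_stats <- function(map_volume, roi_mask = NULL) {
  x <- extract_roi_values(map_volume, roi_mask)
  if (length(x) == 0) stop("empty ROI: no voxels to characterize")
  if (any(!is.finite(x))) stop("non-finite map values inside the ROI")
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  out <- list(mean = mu,
              sd = if (n > 1) stats::sd(x) else 0,
              skewness = NA_real_, kurtosis = NA_real_,
              n_voxels = n, defined = FALSE)
  if (n >= 3 && m2 > 0) {
    out$skewness <- mean(d^3) / m2^1.5
    out$kurtosis <- mean(d^4) / m2^2
    out$defined <- TRUE
  }
  structure(out, class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> n=%d mean=%.4g sd=%.4g skew=%.4g kurt=%.4g\n",
              x$n_voxels, x$mean, x$sd, x$skewness, x$kurtosis))
  invisible(x)
}

extract_roi_values <- function(map_volume, roi_mask) {
  if (is.null(roi_mask)) return(as.numeric(map_volume))
  if (is.array(roi_mask) || is.logical(roi_mask)) {
    m <- as_mask(roi_mask)
    if (!identical(dim(m), dim(map_volume)))
      stop("mask and map shapes differ")
    return(as.numeric(map_volume[m]))
  }
  as.numeric(map_volume[as.integer(roi_mask)])
}

#' Density-normalized histogram of ROI values
#'
#' Histogram heights are densities: the sum of height x bin-width over bins
#' equals 1 for the values falling inside the bin range (values outside
#' `bin_edges` are dropped). Bins are left-open, right-closed, with the lowest
#' edge included.
#'
#' @param map_volume Numeric array or vector.
#' @param roi_mask Mask or indices as in [compute_roi_stats()].
#' @param bin_edges Strictly increasing numeric vector of edges.
#' @return Data frame with `mid`, `lower`, `upper`, `density`.
#' @export
compute_pdf <- function(map_volume, roi_mask = NULL, bin_edges) {
  x <- extract_roi_values(map_volume, roi_mask)
  if (length(x) == 0) stop("empty ROI: nothing to histogram")
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  x <- x[x >= bin_edges[1] & x <= bin_edges[length(bin_edges)]]
  if (length(x) == 0) stop("no ROI values fall inside the bin range")
  h <- graphics::hist(x, breaks = bin_edges, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  data.frame(mid = h$mids,
             lower = bin_edges[-length(bin_edges)],
             upper = bin_edges[-1],
             density = h$density)
}

#' Per-patient ROI statistics table for a cohort
#'
#' One row per (patient, map, roi) with the four first-order statistics.
#' Patients whose ROI is empty (e.g. no T1e) contribute no row for that ROI.
#'
#' @param cohort List of [patient_record()]s with derived ROIs.
#' @param maps Which maps to characterize.
#' @param rois Which ROIs to characterize.
#' @return Data frame with columns `patient_id`, `has_enhancement`, `map`,
#'   `roi`, `mean`, `sd`, `skewness`, `kurtosis`, `n_voxels`.
#' @export
cohort_roi_stats <- function(cohort, maps = c("t1", "t2", "pd"),
                             rois = c("nwm", "per", "t2h", "t1e")) {
  rows <- list()
  for (rec in cohort) {
    for (roi in rois) {
      m <- rec$rois[[roi]]
      if (is.null(m) || !any(m)) next
      for (mp in maps) {
        s <- compute_roi_stats(rec$maps[[mp]], m)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = rec$maps$patient_id,
          has_enhancement = rec$has_enhancement,
          map = mp, roi = roi, mean = s$mean, sd = s$sd,
          skewness = s$skewness, kurtosis = s$kurtosis,
          n_voxels = s$n_voxels)
      }
    }
  }
  do.call(rbind, rows)
}

#' Cohort-level summary of per-patient ROI statistics
#'
#' For each (map, roi, statistic) cell, the mean across patients and a
#' t-based 95% confidence-interval half-width
#' `t(0.975, n-1) * SD_patients / sqrt(n)`. Patients missing an ROI are
#' excluded from that ROI's cells.
#'
#' @param per_patient_stats Data frame from [cohort_roi_stats()].
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with `map`, `roi`, `statistic`, `mean`, `ci_halfwidth`,
#'   `n_patients`.
#' @export
summarize_cohort <- function(per_patient_stats, conf_level = 0.95) {
  stats_names <- c("mean", "sd", "skewness", "kurtosis")
  rows <- list()
  for (mp in unique(per_patient_stats$map)) {
    for (roi in unique(per_patient_stats$roi)) {
      sub <- per_patient_stats[per_patient_stats$map == mp &
                               per_patient_stats$roi == roi, ]
      if (nrow(sub) < 2) {
        if (nrow(sub) == 1)
          message("note: ROI '", roi, "' (", mp,
                  ") has a single patient; skipped from the summary")
        next
      }
      for (st in stats_names) {
        v <- sub[[st]]
        v <- v[is.finite(v)]
        n <- length(v)
        if (n < 2) next
        hw <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
          stats::sd(v) / sqrt(n)
        rows[[length(rows) + 1L]] <- data.frame(
          map = mp, roi = roi, statistic = st,
          mean = mean(v), ci_halfwidth = hw, n_patients = n)
      }
    }
  }
  do.call(rbind, rows)
}
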