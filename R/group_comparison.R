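#' Wilcoxon signed-rank test with exact enumeration p-values
#'
#' Paired two-sided test. Zero differences are dropped (standard Wilcoxon
#' practice); absolute differences receive average ranks under ties; the
#' statistic W is the sum of the ranks of the positive differences. For
#' `n <= exact_limit` pairs the two-sided p-value is exact over the 2^n
#' equiprobable sign assignments (computed by convolving the rank masses,
#' which is equivalent to full enumeration and also valid under ties); above
#' that a normal approximation with tie correction is used. Two-sided
#' p = min(1, 2 * min(P(W <= w), P(W >= w))).
#'
#' @param x_values,y_values Paired numeric vectors of equal length.
#' @param exact_limit Largest n for which the exact distribution is used.
#' @return Object of class `paired_test`: `statistic` (W), `p_value`,
#'   `n_pairs` (after zero-difference removal), `method`.
#' @export
wilcoxon_signed_rank <- function(x_values, y_values, exact_limit = 20) {
  if (length(x_values) != length(y_values))
    stop("x_values and y_values must have equal length")
  if (length(x_values) < 1) stop("at least one pair required")
  d <- x_values - y_values
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("degenerate test: all paired differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of W over the 2^n sign assignments; ranks are multiples
    # of 1/2, so the support lives on the integer grid of 2W
    counts <- signed_rank_distribution(r)
    grid <- seq(0, sum(2 * r))
    tol <- 1e-9
    p_le <- sum(counts[grid <= 2 * w + tol]) / 2^n
    p_ge <- sum(counts[grid >= 2 * w - tol]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  structure(list(statistic = w, p_value = p, n_pairs = n, method = method),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("<paired_test> W=%g  p=%.4g  n=%d  (%s)\n",
              x$statistic, x$p_value, x$n_pairs, x$method))
  invisible(x)
}

# Mass (in counts out of 2^n) of 2W on the integer grid 0..sum(2r),
# by convolution over each rank's {0, 2r_i} contribution.
signed_rank_distribution <- function(ranks) {
  total <- round(sum(2 * ranks))
  f <- numeric(total + 1)
  f[1] <- 1
  for (tr in round(2 * ranks)) {
    g <- f
    g[(tr + 1):(total + 1)] <- g[(tr + 1):(total + 1)] +
      f[1:(total + 1 - tr)]
    f <- g
  }
  f
}

#' Paired ROI-vs-ROI comparison of a per-patient statistic
#'
#' Pairs each patient's value of `statistic` for `map` in `roi_a` with the
#' same patient's value in `roi_b` and runs [wilcoxon_signed_rank()].
#' Patients lacking either ROI (e.g. no T1e) are excluded.
#'
#' @param per_patient_stats Data frame from [cohort_roi_stats()].
#' @param roi_a,roi_b ROI names.
#' @param map Map name (`"t1"`, `"t2"`, `"pd"`).
#' @param statistic One of `"mean"`, `"sd"`, `"skewness"`, `"kurtosis"`.
#' @return A `paired_test` object.
#' @export
compare_rois <- function(per_patient_stats, roi_a, roi_b, map, statistic) {
  a <- per_patient_stats[per_patient_stats$roi == roi_a &
                         per_patient_stats$map == map, ]
  b <- per_patient_stats[per_patient_stats$roi == roi_b &
                         per_patient_stats$map == map, ]
  common <- intersect(a$patient_id, b$patient_id)
  if (length(common) < 2)
    stop("insufficient data: fewer than 2 patients have both ROIs")
  av <- a[[statistic]][match(common, a$patient_id)]
  bv <- b[[statistic]][match(common, b$patient_id)]
  keep <- is.finite(av) & is.finite(bv)
  if (sum(keep) < 2)
    stop("insufficient data: fewer than 2 finite pairs")
  wilcoxon_signed_rank(av[keep], bv[keep])
}

#' Compare a per-patient feature between two patient groups
#'
#' With equal group sizes the groups are paired by index order within each
#' group and a signed-rank test is run; an unpaired Wilcoxon rank-sum test is
#' always computed as a cross-check (the imposed pairing is an assumption,
#' not a property of the data). Unequal group sizes fall back to the
#' rank-sum test with a warning.
#'
#' @param feature_values Numeric vector, one value per patient.
#' @param group_labels Logical or two-level vector splitting the patients.
#' @return A `paired_test` object (or rank-sum fallback of class
#'   `group_test`) with an added `rank_sum_p` cross-check element.
#' @export
compare_groups <- function(feature_values, group_labels) {
  g <- as.factor(group_labels)
  if (nlevels(g) != 2) stop("group_labels must have exactly two levels")
  a <- feature_values[g == levels(g)[1]]
  b <- feature_values[g == levels(g)[2]]
  rs <- suppressWarnings(stats::wilcox.test(a, b))
  if (length(a) != length(b)) {
    warning("unequal group sizes: reporting the rank-sum test only")
    return(structure(list(statistic = unname(rs$statistic),
                          p_value = rs$p.value,
                          n_pairs = NA_integer_, method = "rank-sum",
                          rank_sum_p = rs$p.value),
                     class = c("group_test", "paired_test")))
  }
  out <- wilcoxon_signed_rank(a, b)
  out$rank_sum_p <- rs$p.value
  out
}
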