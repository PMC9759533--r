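toy_maps <- function(t1, t2, pd = t2 * 0 + 70) {
  dm <- c(length(t1), 1, 1)
  quant_map_set("toy", array(t1, dm), array(t2, dm), array(pd, dm))
}

test_that("composite metrics match hand arithmetic", {
  maps <- toy_maps(1000, 100)
  expect_equal(as.numeric(compute_metric(maps, "normT1T2")), 1004.9876,
               tolerance = 1e-4)
  expect_equal(as.numeric(compute_metric(maps, "normlog")),
               sqrt(log(1000)^2 + log(100)^2), tolerance = 1e-12)
  expect_equal(round(as.numeric(compute_metric(maps, "normlog")), 3), 8.302)
  expect_equal(as.numeric(compute_metric(maps, "normT1T2PD")),
               sqrt(1000^2 + 100^2 + 70^2))
  expect_equal(as.numeric(compute_metric(maps, "normlogT1T2PD")),
               sqrt(log(1000)^2 + log(100)^2 + log(70)^2))
})

test_that("raw metrics ignore the other map; logs mask bad voxels", {
  maps <- toy_maps(c(1000, 900), c(0, 100))
  expect_silent(v <- compute_metric(maps, "t1"))
  expect_equal(as.numeric(v), c(1000, 900))
  expect_warning(nl <- compute_metric(maps, "normlog"), "1 voxel")
  expect_true(is.na(nl[1, 1, 1]))
  expect_equal(attr(nl, "n_masked"), 1L)
})

test_that("metrics are monotone in T1 above 1 ms", {
  set.seed(3)
  t1 <- stats::runif(50, 2, 2000); t2 <- stats::runif(50, 2, 300)
  up <- toy_maps(t1 * 1.05, t2); base <- toy_maps(t1, t2)
  for (mt in c("normT1T2", "normlog")) {
    expect_true(all(compute_metric(up, mt) >= compute_metric(base, mt)))
  }
})

test_that("ROC handles separable, inverted and tied classes exactly", {
  perfect <- build_roc(c(3, 4), c(1, 2))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$youden$j, 1)
  expect_equal(build_roc(c(1, 3), c(2, 4))$auc, 0.25)
  expect_equal(build_roc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  expect_error(build_roc(numeric(0), 1:3), "at least one")
})

test_that("trapezoidal AUC equals brute-force concordance and the Youden
           point is the exhaustive optimum", {
  set.seed(55)
  for (trial in 1:25) {
    n1 <- sample(200, 1); n0 <- sample(200, 1)
    # mixture of continuous and discretized values to exercise ties
    pos <- round(stats::rnorm(n1, 0.5), sample(0:2, 1))
    neg <- round(stats::rnorm(n0), sample(0:2, 1))
    roc <- build_roc(pos, neg)
    expect_equal(roc$auc, brute_auc(pos, neg), tolerance = 1e-12)
    j <- vapply(roc$thresholds, function(t)
      mean(pos > t) + mean(neg <= t) - 1, numeric(1))
    expect_equal(roc$youden$j, max(j), tolerance = 1e-12)
    expect_equal(roc$youden$threshold,
                 roc$thresholds[which.max(j)])   # lowest-threshold tie-break
    expect_true(all(diff(roc$sensitivity) <= 1e-12))
    expect_true(all(diff(roc$specificity) >= -1e-12))
  }
})

test_that("AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(8)
  pos <- stats::rnorm(300, 1); neg <- stats::rnorm(250)
  ref <- pROC::auc(pROC::roc(
    response = c(rep(1, 300), rep(0, 250)),
    predictor = c(pos, neg), quiet = TRUE, direction = "<"))
  expect_equal(build_roc(pos, neg)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("thresholding is strict and confined to the evaluation mask", {
  vol <- array(c(1, 2, 3, 4), c(4, 1, 1))
  mask <- array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1))
  out <- apply_threshold(vol, 2, mask)
  expect_equal(as.logical(out), c(FALSE, FALSE, TRUE, FALSE))  # strict >
  expect_equal(sum(apply_threshold(vol, 10, mask)), 0)
  expect_error(apply_threshold(vol, 1, array(FALSE, c(4, 1, 1))), "empty")
})

test_that("mask agreement reduces to confusion-matrix arithmetic", {
  dm <- c(10, 10, 1)
  truth <- array(FALSE, dm); truth[1:10, 1, 1] <- TRUE
  pred <- array(FALSE, dm)
  pred[1:7, 1, 1] <- TRUE            # 7 of 10 positives
  pred[1:3, 2, 1] <- TRUE            # 3 of 90 negatives
  ev <- array(TRUE, dm)
  ag <- evaluate_masks(pred, truth, ev)
  expect_equal(ag$sensitivity, 70)
  expect_equal(ag$specificity, 100 * 87 / 90)
  expect_equal(ag$accuracy, 94)

  same <- evaluate_masks(truth, truth, ev)
  expect_equal(c(same$sensitivity, same$specificity, same$accuracy),
               c(100, 100, 100))
  comp <- evaluate_masks(!truth, truth, ev)
  expect_equal(c(comp$sensitivity, comp$specificity, comp$accuracy),
               c(0, 0, 0))
  undef <- evaluate_masks(pred, array(FALSE, dm), ev)
  expect_true(is.na(undef$sensitivity))
  expect_false(undef$defined[["sensitivity"]])
})

test_that("classification questions assemble the documented voxel pools", {
  cohort <- small_cohort()
  rec <- cohort[[1]]
  vals <- pool_question_values(cohort[1], "abn_vs_nwm", "t1")
  expect_length(vals$positive, sum(rec$rois$abn))
  expect_length(vals$negative, sum(rec$rois$nwm))

  vals2 <- pool_question_values(cohort[1], "t1e_vs_rest", "t1")
  expect_length(vals2$positive, sum(rec$rois$t1e))
  expect_length(vals2$negative,
                sum((rec$rois$t2h | rec$rois$per | rec$rois$nwm) &
                      !rec$rois$t1e))

  expect_error(run_question(cohort[8], "t1e_vs_t2h", "t1"),
               "no enhancing voxels")
})

test_that("identical class distributions yield chance-level separation", {
  specs <- default_roi_specs()
  specs$t1$t1e <- specs$t1$t2h
  specs$t2$t1e <- specs$t2$t2h
  cfg <- cohort_config(n_enhancing = 2, n_nonenhancing = 0,
                       grid_shape = c(32, 32, 16),
                       voxel_dims = c(2.5, 2.5, 3),
                       lesion_radius_range = c(8, 9), specs = specs,
                       seed = 12)
  cohort <- generate_cohort(cfg)
  roc <- run_question(cohort, "t1e_vs_t2h", "normT1T2")
  expect_lt(abs(roc$auc - 0.5), 0.08)
})
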