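# deterministic toy feature table: 7 enhancing + 7 non-enhancing patients
toy_table <- function(values, labels = rep(c(TRUE, FALSE), each = 7)) {
  data.frame(patient_id = sprintf("p%02d", seq_along(values)),
             has_enhancement = labels, feat = values)
}

test_that("the feature table has one row per patient and 16 features", {
  cohort <- small_cohort()
  tab <- build_feature_table(cohort)
  expect_equal(nrow(tab), 14)
  fcols <- setdiff(names(tab), c("patient_id", "has_enhancement"))
  expect_length(fcols, 16)
  expect_setequal(
    fcols,
    as.vector(outer(c("t1", "t2", "normT1T2", "normlog"),
                    c("mean", "sd", "skewness", "kurtosis"), paste,
                    sep = "_")))
  expect_equal(sum(tab$has_enhancement), 7)
  expect_true(all(is.finite(as.matrix(tab[fcols]))))
})

test_that("feature rows are label-independent and tolerate degenerate
           statistics", {
  cohort <- small_cohort()
  rec <- cohort[[1]]
  relabeled <- rec
  relabeled$rois <- roi_set(rec$rois$t2h | rec$rois$t1e,
                            array(FALSE, dim(rec$rois$t1e)), rec$rois$wm,
                            abn = rec$rois$abn, per = rec$rois$per,
                            nwm = rec$rois$nwm)
  relabeled <- patient_record(rec$maps, relabeled$rois)
  a <- build_feature_table(list(rec))
  b <- build_feature_table(list(relabeled))
  fcols <- setdiff(names(a), c("patient_id", "has_enhancement"))
  expect_equal(a[fcols], b[fcols])
  expect_false(b$has_enhancement)

  flat <- rec
  flat$maps$t1[] <- 1000; flat$maps$t2[] <- 100; flat$maps$pd[] <- 70
  row <- build_feature_table(list(flat))
  expect_equal(row$t1_sd, 0)
  expect_true(is.na(row$t1_skewness))
})

test_that("leave-pair-out enumerates all pairs and pools correctly", {
  set.seed(2)
  tab <- toy_table(stats::rnorm(14))
  cv <- leave_pair_out_cv(tab, "feat")
  expect_equal(cv$n_folds, 49L)
  expect_true(all(cv$occurrence$times_held_out == 7L))
  expect_true(all(cv$occurrence$times_classified_enhancing <=
                    cv$occurrence$times_held_out))
  # pooled accuracy consistent with the occurrence table
  tp <- sum(cv$occurrence$times_classified_enhancing[
    cv$occurrence$has_enhancement])
  fp <- sum(cv$occurrence$times_classified_enhancing[
    !cv$occurrence$has_enhancement])
  expect_equal(cv$sensitivity, 100 * tp / 49)
  expect_equal(cv$specificity, 100 * (49 - fp) / 49)
  expect_equal(cv$accuracy, 100 * (tp + 49 - fp) / 98)
})

test_that("separable and exchangeable features hit the theoretical
           extremes", {
  sep <- leave_pair_out_cv(toy_table(c(11:17, 1:7)), "feat")
  expect_true(all(sep$fold_aucs == 1))
  expect_equal(sep$sensitivity, 100)
  expect_equal(sep$specificity, 100)
  expect_equal(sep$accuracy, 100)

  flat <- leave_pair_out_cv(toy_table(rep(3, 14)), "feat")
  expect_true(all(flat$fold_aucs == 0.5))

  expect_error(leave_pair_out_cv(toy_table(c(NA, stats::rnorm(13))), "feat"),
               "non-finite")
  expect_error(leave_pair_out_cv(toy_table(1:3, labels = rep(FALSE, 3)),
                                 "feat"), "non-empty")
})

test_that("a label-independent feature averages to chance AUC", {
  set.seed(64)
  mean_aucs <- replicate(30, {
    tab <- toy_table(stats::rnorm(14), labels = sample(rep(c(TRUE, FALSE),
                                                           each = 7)))
    leave_pair_out_cv(tab, "feat")$mean_auc
  })
  expect_lt(abs(mean(mean_aucs) - 0.5), 0.06)
})

test_that("prediction summary ranks features by mean AUC then accuracy", {
  mk <- function(feature, auc, acc) structure(
    list(feature = feature, mean_auc = auc, sd_auc = 0.01, fold_aucs = auc,
         sensitivity = acc, specificity = acc, accuracy = acc,
         n_folds = 49L, occurrence = NULL), class = "cv_summary")
  s <- summarize_prediction(list(mk("a", 0.68, 70), mk("b", 0.54, 99)))
  expect_equal(s$best_feature, "a")
  expect_true(s$table$best[s$table$feature == "a"])
  s2 <- summarize_prediction(list(mk("a", 0.6, 50), mk("b", 0.6, 70)))
  expect_equal(s2$best_feature, "b")   # AUC tie broken by accuracy
  one <- summarize_prediction(list(mk("only", 0.7, 70)))
  expect_equal(nrow(one$table), 1)
  expect_error(summarize_prediction(list()), "at least one")
})
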