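test_that("moment inversion reproduces the targets analytically", {
  spec <- roi_spec(993.16, 294.04, target_skewness = 2.64)
  p <- lognormal_params(spec)
  w <- exp(p$sdlog^2)
  lmean <- exp(p$meanlog + p$sdlog^2 / 2)
  expect_equal(p$shift + lmean, 993.16, tolerance = 1e-10)         # mean
  expect_equal(lmean * sqrt(w - 1), 294.04, tolerance = 1e-8)      # sd
  expect_equal((w + 2) * sqrt(w - 1), 2.64, tolerance = 1e-8)      # skewness
  expect_equal(p$skewness, (exp(p$sdlog^2) + 2) * sqrt(exp(p$sdlog^2) - 1))

  # without a skewness target the stated shift is honored
  p0 <- lognormal_params(roi_spec(100, 20, shift = 30))
  expect_equal(p0$shift, 30)
  expect_equal(p0$shift + exp(p0$meanlog + p0$sdlog^2 / 2), 100)
})

test_that("sampler recovers mean and SD and respects the support bound", {
  spec <- roi_spec(1353.78, 294.68, target_skewness = 1.23)
  p <- lognormal_params(spec)
  set.seed(31)
  x <- sample_roi_values(spec, 1e5)
  se_mean <- 294.68 / sqrt(1e5)
  se_sd <- 294.68 / 2 * sqrt((p$kurtosis - 1) / 1e5)
  expect_lt(abs(mean(x) - 1353.78), 5 * se_mean)
  expect_lt(abs(stats::sd(x) - 294.68), 5 * se_sd)
  expect_true(all(x > p$shift))
})

test_that("degenerate and infeasible specs are handled", {
  set.seed(2)
  x <- sample_roi_values(roi_spec(500, 1e-6), 100)
  expect_true(all(abs(x - 500) < 1e-4))
  expect_error(roi_spec(100, 10, target_skewness = -1), "parameter error")
  expect_error(roi_spec(100, 10, target_skewness = 0), "parameter error")
  expect_error(roi_spec(100, -1), "positive")
})

test_that("patient generation is deterministic and respects the core
           fraction", {
  cfg <- small_cohort_config()
  a <- generate_patient(cfg, TRUE, "p", seed = 77)
  b <- generate_patient(cfg, TRUE, "p", seed = 77)
  expect_identical(a$maps$t1, b$maps$t1)
  expect_identical(a$rois$t1e, b$rois$t1e)

  no_enh <- generate_patient(cfg, FALSE, "p", seed = 78)
  expect_equal(sum(no_enh$rois$t1e), 0)
  expect_false(no_enh$has_enhancement)

  # fine isotropic grid so discretization error is small
  cfg_fine <- cohort_config(grid_shape = c(44, 44, 44),
                            voxel_dims = c(1, 1, 1),
                            lesion_radius_range = c(7, 7),
                            core_fraction_range = c(0.30, 0.30),
                            radius_mm = 8, seed = 1)
  rec <- generate_patient(cfg_fine, TRUE, "p", seed = 5)
  lesion <- sum(rec$rois$abn)
  expect_gt(lesion, 800)
  expect_equal(sum(rec$rois$t1e) / lesion, 0.30, tolerance = 0.1)
})

test_that("cohort generation reproduces the study design deterministically", {
  cohort <- small_cohort()
  expect_length(cohort, 14)
  enh <- vapply(cohort, `[[`, logical(1), "has_enhancement")
  expect_equal(sum(enh), 7)
  expect_identical(enh, rep(c(TRUE, FALSE), each = 7))

  again <- generate_cohort(small_cohort_config())
  counts <- function(ch) vapply(ch, function(r) sum(r$rois$t2h), integer(1))
  expect_identical(counts(cohort), counts(again))
  expect_identical(cohort[[3]]$maps$t2, again[[3]]$maps$t2)

  solo <- generate_cohort(cohort_config(n_enhancing = 0, n_nonenhancing = 1,
                                        grid_shape = c(32, 32, 16),
                                        voxel_dims = c(2.5, 2.5, 3),
                                        lesion_radius_range = c(7, 9),
                                        seed = 3))
  expect_length(solo, 1)
  expect_false(solo[[1]]$has_enhancement)
})

test_that("default targets preserve the study's ROI ordering", {
  specs <- default_roi_specs()
  for (mp in c("t1", "t2")) {
    m <- vapply(specs[[mp]][c("nwm", "per", "t2h", "t1e")],
                `[[`, numeric(1), "target_mean")
    expect_true(all(diff(m) > 0))
  }
})

test_that("a generated patient fails loudly when the lesion cannot fit", {
  cfg <- cohort_config(grid_shape = c(12, 12, 6), voxel_dims = c(1, 1, 1),
                       lesion_radius_range = c(8, 8), seed = 1)
  expect_error(generate_patient(cfg, FALSE, "p", seed = 1),
               "geometry error")
})
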