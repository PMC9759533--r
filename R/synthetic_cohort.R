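#' Distribution target for one (ROI, map) cell
#'
#' Specifies the first-order targets a synthetic ROI should reproduce: mean
#' and SD exactly (by moment inversion of a shifted lognormal) and, when
#' given, Fisher skewness analytically. Units follow the map: ms for T1/T2,
#' percent units for PD.
#'
#' @param target_mean,target_sd Targets in map units; `target_sd > 0`.
#' @param target_skewness Optional Fisher g1 target; must be > 0 (the
#'   lognormal family is right-skewed). When given, the support shift is
#'   solved from it; otherwise `shift` is used as-is.
#' @param shift Lower bound of the support (map units), default 0.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(target_mean, target_sd, target_skewness = NULL,
                     shift = 0) {
  if (target_sd <= 0) stop("target_sd must be positive")
  if (!is.null(target_skewness) && target_skewness <= 0)
    stop("parameter error: lognormal family requires skewness > 0")
  if (is.null(target_skewness) && target_mean <= shift)
    stop("target_mean must exceed shift")
  structure(list(target_mean = target_mean, target_sd = target_sd,
                 target_skewness = target_skewness, shift = shift),
            class = "roi_spec")
}

#' Solve the shifted-lognormal parameters for a spec
#'
#' For `X = shift + exp(N(meanlog, sdlog^2))` the first two moments are
#' matched exactly: `sdlog^2 = log(1 + sd^2/(mean - shift)^2)`,
#' `meanlog = log(mean - shift) - sdlog^2/2`. When a skewness target g1 is
#' given, `w = exp(sdlog^2)` is solved from the closed form
#' `g1 = (w + 2) * sqrt(w - 1)` and the shift from the SD constraint
#' `shift = mean - sd / sqrt(w - 1)`. The analytic Fisher skewness and
#' Pearson (non-excess) kurtosis of the fitted distribution are returned for
#' use in sampling-error bounds.
#'
#' @param spec A [roi_spec()].
#' @return List with `meanlog`, `sdlog`, `shift`, `skewness`, `kurtosis`.
#' @export
lognormal_params <- function(spec) {
  stopifnot(inherits(spec, "roi_spec"))
  m <- spec$target_mean; s <- spec$target_sd
  if (!is.null(spec$target_skewness)) {
    g1 <- spec$target_skewness
    f <- function(w) (w + 2) * sqrt(w - 1) - g1
    upper <- 2
    while (f(upper) < 0) upper <- upper * 2
    w <- stats::uniroot(f, c(1 + 1e-12, upper), tol = 1e-12)$root
    shift <- m - s / sqrt(w - 1)
  } else {
    shift <- spec$shift
    w <- 1 + s^2 / (m - shift)^2
  }
  sdlog <- sqrt(log(w))
  meanlog <- log(m - shift) - sdlog^2 / 2
  list(meanlog = meanlog, sdlog = sdlog, shift = shift,
       skewness = (w + 2) * sqrt(w - 1),
       kurtosis = w^4 + 2 * w^3 + 3 * w^2 - 3)
}

#' Sample synthetic voxel values for one ROI
#'
#' Draws i.i.d. values from the shifted lognormal fitted by
#' [lognormal_params()], so the population mean and SD equal the spec targets
#' exactly and, when a skewness target is set, the population Fisher skewness
#' matches it analytically. Samples are strictly greater than the shift.
#'
#' @param spec A [roi_spec()].
#' @param n Number of values (>= 1).
#' @return Numeric vector of length `n`.
#' @export
sample_roi_values <- function(spec, n) {
  stopifnot(n >= 1)
  p <- lognormal_params(spec)
  p$shift + stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
}

#' Default distribution targets for the synthetic cohort
#'
#' T1 and T2 targets are the cohort-level per-ROI means, SDs and skewnesses of
#' a 14-patient treated-glioma study (T1e has the highest T1 and T2, then T2h,
#' PER and nWM; all distributions right-skewed). PD targets are synthetic
#' placeholders chosen to be qualitatively consistent with that study (T2h and
#' T1e similar and above nWM/PER); they are configurable and do not drive any
#' headline analysis.
#'
#' @return Nested list `specs[[map]][[roi]]` of [roi_spec()] objects, for maps
#'   `t1`, `t2`, `pd` and ROIs `nwm`, `per`, `t2h`, `t1e`.
#' @export
default_roi_specs <- function() {
  list(
    t1 = list(
      nwm = roi_spec(993.16, 294.04, 2.64),
      per = roi_spec(1056.78, 315.16, 2.27),
      t2h = roi_spec(1353.78, 294.68, 1.23),
      t1e = roi_spec(1713.30, 448.03, 1.00)),
    t2 = list(
      nwm = roi_spec(92.33, 48.90, 10.72),
      per = roi_spec(103.82, 63.56, 8.10),
      t2h = roi_spec(152.25, 64.63, 4.62),
      t1e = roi_spec(180.05, 130.81, 3.57)),
    pd = list(
      nwm = roi_spec(68, 6, 0.5),
      per = roi_spec(70, 7, 0.5),
      t2h = roi_spec(78, 8, 0.5),
      t1e = roi_spec(80, 9, 0.5)))
}

#' Configuration of the synthetic cohort generator
#'
#' @param n_enhancing,n_nonenhancing Patient counts per group (default 7 + 7,
#'   the study's design).
#' @param grid_shape 3-vector of voxel counts.
#' @param voxel_dims 3-vector of voxel edge lengths (mm).
#' @param lesion_radius_range Range (mm) the lesion radius is drawn from.
#' @param core_fraction_range Range of the enhancing-core volume fraction.
#' @param specs Nested `[[map]][[roi]]` list of [roi_spec()]s; defaults to
#'   [default_roi_specs()].
#' @param radius_mm Perilesional shell radius (mm).
#' @param mean_jitter Relative SD of optional per-patient jitter applied to
#'   each spec's target mean (0 disables it; pooled cohort moments then equal
#'   the targets).
#' @param seed Integer seed; per-patient substreams are derived from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_enhancing = 7, n_nonenhancing = 7,
                          grid_shape = c(48, 48, 24),
                          voxel_dims = c(1.75, 1.75, 2.5),
                          lesion_radius_range = c(8, 12),
                          core_fraction_range = c(0.2, 0.4),
                          specs = default_roi_specs(),
                          radius_mm = 10, mean_jitter = 0, seed = 42) {
  stopifnot(n_enhancing >= 0, n_nonenhancing >= 0,
            length(grid_shape) == 3, length(voxel_dims) == 3,
            all(voxel_dims > 0), all(lesion_radius_range > 0),
            all(core_fraction_range > 0), all(core_fraction_range < 1),
            radius_mm > 0, mean_jitter >= 0)
  structure(list(n_enhancing = as.integer(n_enhancing),
                 n_nonenhancing = as.integer(n_nonenhancing),
                 grid_shape = as.integer(grid_shape),
                 voxel_dims = as.numeric(voxel_dims),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 core_fraction_range = as.numeric(core_fraction_range),
                 specs = specs, radius_mm = radius_mm,
                 mean_jitter = mean_jitter, seed = as.integer(seed)),
            class = "cohort_config")
}

# Logical ellipsoid mask: voxel centres (world mm) within the ellipsoid.
ellipsoid_mask <- function(grid_shape, voxel_dims, center, semi_axes) {
  cx <- (seq_len(grid_shape[1]) - 1) * voxel_dims[1]
  cy <- (seq_len(grid_shape[2]) - 1) * voxel_dims[2]
  cz <- (seq_len(grid_shape[3]) - 1) * voxel_dims[3]
  dx2 <- ((cx - center[1]) / semi_axes[1])^2
  dy2 <- ((cy - center[2]) / semi_axes[2])^2
  dz2 <- ((cz - center[3]) / semi_axes[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' Generate one synthetic patient
#'
#' Builds a white-matter ellipsoid on the grid, places an ellipsoidal T2h
#' lesion inside it and, for enhancing patients, carves an inner T1e core
#' whose volume fraction of the lesion is drawn from
#' `core_fraction_range`. Derived ROIs are populated via [derive_rois()], and
#' each map is filled voxel-wise by [sample_roi_values()] with that ROI's
#' spec (background voxels reuse the nWM spec so maps stay positive
#' everywhere).
#'
#' @param config A [cohort_config()].
#' @param enhancing Logical: carve a T1e core?
#' @param patient_id Identifier string.
#' @param seed Optional integer seed for this patient's substream.
#' @return A [patient_record()] with derived ROIs.
#' @export
generate_patient <- function(config, enhancing, patient_id = "synthetic",
                             seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  gs <- config$grid_shape; vd <- config$voxel_dims
  extent <- (gs - 1) * vd
  wm_center <- extent / 2
  wm_semi <- extent * 0.42
  wm <- ellipsoid_mask(gs, vd, wm_center, wm_semi)

  r <- stats::runif(1, config$lesion_radius_range[1],
                    config$lesion_radius_range[2])
  semi <- r * (1 + stats::runif(3, -0.15, 0.15))
  # smaller z-jitter: thin slabs leave little headroom for lesion + shell
  center <- wm_center + stats::runif(3, -1, 1) * c(0.25, 0.25, 0.1) * wm_semi
  if (any(center - semi - config$radius_mm < 0) ||
      any(center + semi + config$radius_mm > extent))
    stop("geometry error: lesion plus perilesional shell does not fit the grid")
  lesion <- ellipsoid_mask(gs, vd, center, semi)
  if (!any(lesion)) stop("geometry error: lesion contains no voxel centre")

  if (enhancing) {
    cf <- stats::runif(1, config$core_fraction_range[1],
                       config$core_fraction_range[2])
    t1e <- ellipsoid_mask(gs, vd, center, semi * cf^(1 / 3))
    if (!any(t1e))
      stop("geometry error: enhancing core contains no voxel centre")
    t2h <- lesion & !t1e
  } else {
    t1e <- array(FALSE, gs)
    t2h <- lesion
  }

  affine <- diag(c(vd, 1))
  maps <- list()
  abn <- t2h | t1e
  per <- derive_per(abn, vd, config$radius_mm)
  nwm <- derive_nwm(wm, abn, per)
  regions <- list(t1e = t1e, t2h = t2h, per = per, nwm = nwm,
                  bg = !(abn | per | nwm))
  for (mp in c("t1", "t2", "pd")) {
    vol <- array(NA_real_, gs)
    for (rg in names(regions)) {
      idx <- which(regions[[rg]])
      if (!length(idx)) next
      spec <- config$specs[[mp]][[if (rg == "bg") "nwm" else rg]]
      if (config$mean_jitter > 0) {
        m <- spec$target_mean *
          (1 + stats::rnorm(1, 0, config$mean_jitter))
        spec <- roi_spec(m, spec$target_sd, spec$target_skewness, spec$shift)
      }
      vol[idx] <- sample_roi_values(spec, length(idx))
    }
    maps[[mp]] <- vol
  }
  record <- patient_record(
    quant_map_set(patient_id, maps$t1, maps$t2, maps$pd, affine),
    roi_set(t2h, t1e, wm, abn = abn, per = per, nwm = nwm))
  record
}

#' Generate the full synthetic cohort
#'
#' Produces `n_enhancing + n_nonenhancing` patient records with per-patient
#' jitter of lesion size and position, reproducible from `config$seed`
#' (per-patient substreams are derived deterministically from it).
#'
#' @param config A [cohort_config()].
#' @return List of [patient_record()]s, enhancing patients first.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_enhancing + config$n_nonenhancing
  records <- vector("list", n)
  for (i in seq_len(n)) {
    enhancing <- i <= config$n_enhancing
    seed_i <- as.integer((as.numeric(config$seed) + 99991 * i) %%
                           2147483647)
    records[[i]] <- generate_patient(
      config, enhancing,
      patient_id = sprintf("syn%02d", i), seed = seed_i)
  }
  records
}
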