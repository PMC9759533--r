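#' Quantitative map set for one patient
#'
#' Bundles a patient's coregistered quantitative volumes: T1 (ms), T2 (ms) and
#' proton density (percent units), together with the voxel-to-world affine.
#' All three volumes must share one shape; voxel edge lengths (mm) are derived
#' from the affine column norms. Values are held as double precision
#' internally regardless of the on-disk type, since downstream metrics take
#' logarithms and Euclidean norms of the raw values.
#'
#' @param patient_id Character scalar identifying the patient.
#' @param t1,t2,pd 3-D numeric arrays of identical dimensions.
#' @param affine 4x4 voxel-to-world transform (mm). Defaults to identity.
#' @return An object of class `quant_map_set` with elements `patient_id`,
#'   `t1`, `t2`, `pd`, `affine` and `voxel_dims`.
#' @export
quant_map_set <- function(patient_id, t1, t2, pd, affine = diag(4)) {
  t1 <- as_volume(t1); t2 <- as_volume(t2); pd <- as_volume(pd)
  if (!identical(dim(t1), dim(t2)) || !identical(dim(t1), dim(pd)))
    stop("t1, t2 and pd volumes must share one shape")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  vd <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(!is.finite(vd)) || any(vd <= 0))
    stop("affine implies non-positive voxel dimensions")
  structure(
    list(patient_id = as.character(patient_id), t1 = t1, t2 = t2, pd = pd,
         affine = affine, voxel_dims = vd),
    class = "quant_map_set")
}

#' @export
print.quant_map_set <- function(x, ...) {
  cat("<quant_map_set> patient", x$patient_id, "\n")
  cat("  grid:", paste(dim(x$t1), collapse = " x "),
      " voxel (mm):", paste(signif(x$voxel_dims, 4), collapse = " x "), "\n")
  invisible(x)
}

#' Region-of-interest mask set
#'
#' Holds the raw masks (T2 hyperintensity `t2h`, T1w enhancement `t1e`, white
#' matter `wm`) and, once derived, the abnormal-tissue union `abn`, the
#' perilesional shell `per` and normal-appearing white matter `nwm`. All masks
#' are stored as logical arrays on the map grid. Derived members may be `NULL`
#' until [derive_rois()] is called.
#'
#' @param t2h,t1e,wm Logical (or 0/1 numeric) 3-D arrays of one shape.
#' @param abn,per,nwm Optional derived masks.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(t2h, t1e, wm, abn = NULL, per = NULL, nwm = NULL) {
  t2h <- as_mask(t2h); t1e <- as_mask(t1e); wm <- as_mask(wm)
  if (!identical(dim(t2h), dim(t1e)) || !identical(dim(t2h), dim(wm)))
    stop("all masks must share one shape")
  out <- structure(
    list(t2h = t2h, t1e = t1e, wm = wm,
         abn = if (!is.null(abn)) as_mask(abn),
         per = if (!is.null(per)) as_mask(per),
         nwm = if (!is.null(nwm)) as_mask(nwm)),
    class = "roi_set")
  validate_roi_set(out)
  out
}

validate_roi_set <- function(rois) {
  d <- dim(rois$t2h)
  for (nm in c("abn", "per", "nwm")) {
    m <- rois[[nm]]
    if (is.null(m)) next
    if (!identical(dim(m), d)) stop("mask '", nm, "' shape differs from t2h")
  }
  if (!is.null(rois$abn)) {
    if (!identical(rois$abn, rois$t2h | rois$t1e))
      stop("abn must equal the voxel-wise union of t2h and t1e")
    if (!is.null(rois$per) && any(rois$per & rois$abn))
      stop("per must be disjoint from abn")
    if (!is.null(rois$nwm)) {
      if (any(rois$nwm & rois$abn)) stop("nwm must be disjoint from abn")
      if (!is.null(rois$per) && any(rois$nwm & rois$per))
        stop("nwm must be disjoint from per")
      if (any(rois$nwm & !rois$wm)) stop("nwm must be a subset of wm")
    }
  }
  invisible(rois)
}

#' Patient record: maps plus masks
#'
#' @param maps A [quant_map_set()].
#' @param rois A [roi_set()] on the same grid.
#' @return An object of class `patient_record` with a `has_enhancement` flag,
#'   true iff the raw `t1e` mask contains at least one voxel.
#' @export
patient_record <- function(maps, rois) {
  stopifnot(inherits(maps, "quant_map_set"), inherits(rois, "roi_set"))
  if (!identical(dim(maps$t1), dim(rois$t2h)))
    stop("maps and masks must share one grid")
  structure(
    list(maps = maps, rois = rois, has_enhancement = sum(rois$t1e) > 0),
    class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record>", x$maps$patient_id,
      if (x$has_enhancement) "(enhancing)" else "(non-enhancing)", "\n")
  counts <- vapply(x$rois, function(m) if (is.null(m)) NA_integer_ else sum(m),
                   integer(1))
  cat(" ", paste(names(counts), counts, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

as_volume <- function(x) {
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  if (length(dim(x)) != 3L) stop("volumes must be 3-D arrays")
  storage.mode(x) <- "double"
  x
}

# binarize at > 0.5 so interpolation residue in resampled masks is tolerated
as_mask <- function(x, threshold = 0.5) {
  if (is.logical(x)) {
    attributes(x) <- list(dim = dim(x))
  } else {
    x <- as_volume(x) > threshold
  }
  if (length(dim(x)) != 3L) stop("masks must be 3-D arrays")
  x
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  list(data = as_volume(img), affine = aff)
}

#' Load a patient's maps and masks from NIfTI files
#'
#' Reads the three quantitative maps and three raw masks, checks that all six
#' volumes share one grid and (within `affine_tol`) one voxel-to-world
#' transform, binarizes masks at > 0.5 and validates that T1 and T2 are finite
#' and strictly positive inside every raw mask (required by the logarithmic
#' metric). Derived ROIs (`abn`, `per`, `nwm`) are left unpopulated; call
#' [derive_rois()] next.
#'
#' @param t1_path,t2_path,pd_path,t2h_path,t1e_path,wm_path NIfTI file paths.
#' @param patient_id Identifier; defaults to the T1 file name sans extension.
#' @param affine_tol Absolute tolerance on affine entries (default 1e-4,
#'   enough to absorb resampling float noise).
#' @return A [patient_record()].
#' @export
load_patient <- function(t1_path, t2_path, pd_path, t2h_path, t1e_path,
                         wm_path, patient_id = NULL, affine_tol = 1e-4) {
  paths <- c(t1 = t1_path, t2 = t2_path, pd = pd_path,
             t2h = t2h_path, t1e = t1e_path, wm = wm_path)
  vols <- lapply(paths, read_nifti_volume)
  ref <- vols[[1]]
  for (nm in names(vols)) {
    v <- vols[[nm]]
    if (!identical(dim(v$data), dim(ref$data)))
      stop("coregistration error: '", paths[[nm]], "' has shape ",
           paste(dim(v$data), collapse = "x"), ", expected ",
           paste(dim(ref$data), collapse = "x"))
    if (max(abs(v$affine - ref$affine)) > affine_tol)
      stop("coregistration error: affine of '", paths[[nm]],
           "' differs from the T1 map beyond tolerance ", affine_tol)
  }
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(t1_path))
  maps <- quant_map_set(patient_id, vols$t1$data, vols$t2$data, vols$pd$data,
                        ref$affine)
  rois <- roi_set(vols$t2h$data, vols$t1e$data, vols$wm$data)
  inside <- rois$t2h | rois$t1e | rois$wm
  bad <- sum((!is.finite(maps$t1) | maps$t1 <= 0 |
              !is.finite(maps$t2) | maps$t2 <= 0) & inside)
  if (bad > 0)
    stop("data-quality error: ", bad,
         " voxel(s) inside the raw masks have non-finite or non-positive T1/T2")
  patient_record(maps, rois)
}

#' Write a binary mask as NIfTI
#'
#' Written as unsigned 8-bit so a re-read reproduces the mask bit-exactly.
#'
#' @param mask Logical/0-1 3-D array.
#' @param affine 4x4 voxel-to-world transform.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, affine, path) {
  mask <- as_mask(mask)
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  img <- RNifti::`sform<-`(img, structure(as.matrix(affine), code = 2L))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write a quantitative map as NIfTI
#'
#' @param map Numeric 3-D array.
#' @param affine 4x4 voxel-to-world transform.
#' @param path Output path.
#' @param datatype On-disk type; `"double"` keeps a bit-exact round trip.
#' @return `path`, invisibly.
#' @export
save_map <- function(map, affine, path, datatype = "double") {
  img <- RNifti::asNifti(as_volume(map))
  img <- RNifti::`sform<-`(img, structure(as.matrix(affine), code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
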