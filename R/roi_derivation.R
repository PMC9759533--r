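#' Combine the raw lesion masks into the abnormal-tissue region
#'
#' The abnormal-tissue region (ABN) is the voxel-wise union of the
#' non-enhancing T2 hyperintensity (T2h) and the T1w-enhancing region (T1e).
#'
#' @param t2h,t1e Binary 3-D masks of one shape.
#' @return Logical mask of the union.
#' @export
derive_abn <- function(t2h, t1e) {
  t2h <- as_mask(t2h); t1e <- as_mask(t1e)
  if (!identical(dim(t2h), dim(t1e))) stop("t2h and t1e must share one shape")
  t2h | t1e
}

#' Derive the perilesional shell around the abnormal region
#'
#' Returns the set of voxels whose centre lies within `radius_mm` (world
#' units, closed ball) of some ABN voxel centre, minus ABN itself. Anisotropic
#' voxels are handled by scaling each axis offset by its edge length, i.e. the
#' distance is Euclidean in millimetres, not in voxel counts. Implemented as a
#' binary dilation with a ball-shaped structuring element via FFT convolution,
#' which is equivalent to thresholding the exact voxel-centre-to-voxel-centre
#' distance transform at `radius_mm`.
#'
#' @param abn Binary 3-D mask of abnormal tissue.
#' @param voxel_dims 3-vector of voxel edge lengths (mm), all positive.
#' @param radius_mm Shell radius in mm; default 10 (a 1-cm shell).
#' @return Logical mask of the shell; empty when `abn` is empty.
#' @export
derive_per <- function(abn, voxel_dims, radius_mm = 10) {
  abn <- as_mask(abn)
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0))
    stop("voxel_dims must be three positive edge lengths (mm)")
  if (radius_mm <= 0) stop("radius_mm must be positive")
  dilate_ball(abn, voxel_dims, radius_mm) & !abn
}

#' Derive normal-appearing white matter
#'
#' White matter minus the abnormal region and the perilesional shell.
#'
#' @param wm,abn,per Binary 3-D masks of one shape.
#' @return Logical mask `wm & !abn & !per`.
#' @export
derive_nwm <- function(wm, abn, per) {
  wm <- as_mask(wm); abn <- as_mask(abn); per <- as_mask(per)
  if (!identical(dim(wm), dim(abn)) || !identical(dim(wm), dim(per)))
    stop("masks must share one shape")
  wm & !abn & !per
}

#' Populate the derived ROIs of a patient record
#'
#' Fills `abn`, `per` and `nwm` from the raw `t2h`, `t1e` and `wm` masks.
#'
#' @param record A [patient_record()].
#' @param radius_mm Perilesional shell radius in mm (default 10).
#' @return The record with a fully derived [roi_set()].
#' @export
derive_rois <- function(record, radius_mm = 10) {
  stopifnot(inherits(record, "patient_record"))
  r <- record$rois
  abn <- derive_abn(r$t2h, r$t1e)
  per <- derive_per(abn, record$maps$voxel_dims, radius_mm)
  nwm <- derive_nwm(r$wm, abn, per)
  record$rois <- roi_set(r$t2h, r$t1e, r$wm, abn = abn, per = per, nwm = nwm)
  record
}

# Binary dilation of `mask` by a closed world-unit ball of radius `radius`.
# Circular FFT convolution on a zero-padded grid; padding by the kernel
# half-width per axis rules out wrap-around, and counts are integers so the
# 0.5 threshold is safe against FFT round-off.
dilate_ball <- function(mask, voxel_dims, radius) {
  dm <- dim(mask)
  if (!any(mask)) return(array(FALSE, dm))
  hw <- pmin(floor(radius / voxel_dims), dm - 1L)
  offs <- as.matrix(expand.grid(i = -hw[1]:hw[1], j = -hw[2]:hw[2],
                                k = -hw[3]:hw[3]))
  keep <- (offs[, 1] * voxel_dims[1])^2 + (offs[, 2] * voxel_dims[2])^2 +
    (offs[, 3] * voxel_dims[3])^2 <= radius^2 + 1e-9
  offs <- offs[keep, , drop = FALSE]
  pd <- dm + 2L * hw
  A <- array(0, pd)
  A[hw[1] + seq_len(dm[1]), hw[2] + seq_len(dm[2]), hw[3] + seq_len(dm[3])] <-
    as.numeric(mask)
  K <- array(0, pd)
  idx <- cbind(offs[, 1] %% pd[1], offs[, 2] %% pd[2], offs[, 3] %% pd[3]) + 1L
  K[idx] <- 1
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) /
    prod(pd)
  out <- conv[hw[1] + seq_len(dm[1]), hw[2] + seq_len(dm[2]),
              hw[3] + seq_len(dm[3])] > 0.5
  dim(out) <- dm
  out
}
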