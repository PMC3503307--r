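# Micro-CT density descriptors from a HU-calibrated volume and a given
# lung mask (lung/airway segmentation itself is upstream and out of scope).

#' Micro-CT density features MLVI and VBT
#'
#' MLVI (mean lung voxel intensity) is the mean HU value over the masked
#' lung; VBT is the percentage of in-mask voxels strictly below the
#' threshold (default -900 HU, below which healthy murine lung voxels are
#' rare). Airway voxels are assumed to have been removed from the mask
#' already.
#'
#' @param volume an [hu_volume()]
#' @param lung_mask logical 3D array, same shape as the volume
#' @param threshold_hu HU threshold (default -900)
#' @return a `ct_features` list: `MLVI`, `VBT` (percent), `n_voxels`
#' @export
compute_ct_features <- function(volume, lung_mask, threshold_hu = -900) {
  stopifnot(inherits(volume, "hu_volume"))
  if (!identical(dim(volume$voxels), dim(lung_mask)))
    stop("mask shape must match volume shape")
  if (!is.logical(lung_mask)) stop("lung_mask must be logical")
  vals <- volume$voxels[lung_mask]
  n <- length(vals)
  if (n == 0L) stop("empty lung mask")
  structure(list(MLVI = mean(vals),
                 VBT = 100 * sum(vals < threshold_hu) / n,
                 n_voxels = n),
            class = "ct_features")
}

#' @export
print.ct_features <- function(x, ...) {
  cat(sprintf("ct_features: MLVI = %.1f HU | VBT = %.2f%% (n = %d voxels)\n",
              x$MLVI, x$VBT, x$n_voxels))
  invisible(x)
}
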