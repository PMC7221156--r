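# Grey-level discretisation: fixed bin number over the in-ROI min-max range.
#
# Fixed-bin-number quantisation makes raw and z-scored texture features
# directly comparable (the z-score is an affine map, and the binning is
# min-max invariant). Bins are left-open/right-closed with the minimum
# attached to bin 1: level = max(1, ceiling(Ng * (x - min) / range)).
# A constant ROI maps every voxel to level 1.

#' Quantise ROI intensities to Ng grey levels
#'
#' @param vol a [ScanVolume-class].
#' @param roi a [RegionMask-class] with at least 2 foreground voxels.
#' @param Ng number of grey levels (default 32).
#' @return A list of class `QuantizedROI` with elements `levels` (3D integer
#'   array, `NA` outside the ROI), `Ng`, `mask` (logical array), and
#'   `spacing`.
#' @export
quantizeROI <- function(vol, roi, Ng = 32L) {
  stopifnot(is(vol, "ScanVolume"), is(roi, "RegionMask"), Ng >= 1)
  assertSameGrid(roi, vol, "roi mask")
  inroi <- roi@voxels > 0L
  if (sum(inroi) < 2L)
    stop("ROI must contain at least 2 voxels for quantisation", call. = FALSE)
  v <- vol@voxels
  vals <- v[inroi]
  lo <- min(vals); hi <- max(vals)
  lev <- array(NA_integer_, dim = dim(v))
  if (hi > lo) {
    lev[inroi] <- pmax(1L, as.integer(ceiling(Ng * (vals - lo) / (hi - lo))))
  } else {
    lev[inroi] <- 1L
  }
  structure(list(levels = lev, Ng = as.integer(Ng), mask = inroi,
                 spacing = vol@spacing),
            class = "QuantizedROI")
}
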