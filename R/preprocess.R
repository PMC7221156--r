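# Gland-level z-score standardisation.
#
# MR intensities (in particular T2w) have no biological reference scale, so
# each modality of each scan is standardised against its own prostate
# gland: subtract the gland mean, divide by the gland standard deviation.
# The population SD (divide by N) is used; at gland voxel counts the
# difference from the sample SD is immaterial, but a fixed convention keeps
# results reproducible. Voxels outside the gland are mapped with the same
# parameters, so lesion intensities become relative to the whole gland.

#' Gland-level z-score standardisation of a scan
#'
#' Standardises every voxel of `vol` with the mean and population standard
#' deviation of the intensities inside the gland mask, independently per
#' modality and per timepoint.
#'
#' @param vol a [ScanVolume-class].
#' @param gland the gland [RegionMask-class] on the same grid.
#' @return A list with elements `volume` (the standardised
#'   [ScanVolume-class]; gland voxels have mean 0 and SD 1) and `params`
#'   (list with `mean`, `sd`, `modality`, `timepoint`, `patient_id`).
#' @examples
#' v <- ScanVolume(array(rnorm(8^3, 100, 10), dim = c(8, 8, 8)))
#' g <- RegionMask(array(1, dim = c(8, 8, 8)), label = "GLAND")
#' z <- zscoreStandardize(v, g)
#' mean(voxels(z$volume))
#' @export
zscoreStandardize <- function(vol, gland) {
  stopifnot(is(vol, "ScanVolume"), is(gland, "RegionMask"))
  assertSameGrid(gland, vol, what = "gland mask")
  if (gland@label != "GLAND")
    stop("standardisation parameters must come from a GLAND mask", call. = FALSE)
  g <- gland@voxels > 0L
  if (sum(g) < 2L)
    stop("gland mask must contain at least 2 voxels", call. = FALSE)
  vals <- vol@voxels[g]
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))  # population SD
  if (sigma == 0)
    stop("zero gland variance: cannot standardise a constant gland", call. = FALSE)
  out <- vol
  out@voxels <- (vol@voxels - mu) / sigma
  list(volume = out,
       params = list(mean = mu, sd = sigma, modality = vol@modality,
                     timepoint = vol@timepoint, patient_id = vol@patientID))
}
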