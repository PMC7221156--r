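# Habitat convergence: automatic delineation of a restricted-diffusion
# (low-ADC) sub-region seeded by a radiologist lesion mask.
#
# Two variants:
#  * sphere habitat  - grow the search space to a fixed-diameter sphere
#    around the lesion centroid, threshold the ADC map at mu - k*sigma of
#    the sphere-within-gland intensities, keep the largest connected
#    component. May extend beyond the lesion but never beyond the gland.
#  * within-lesion habitat - the largest connected component of the
#    at-or-below-median ADC voxels inside the lesion; always a subset of
#    the lesion.

#' Habitat configuration
#'
#' @param sphereDiameterMM diameter of the spherical search region in mm
#'   (default 15).
#' @param deviationK multiplier k in the sphere threshold `mu - k*sigma`
#'   (default 1). The threshold rule is parameterised because only "the
#'   distributional deviation" is specified for it; k = 1 is this package's
#'   documented convention.
#' @param connectivity 3D connectivity for component analysis: 6, 18 or 26
#'   (default 26).
#' @param medianFraction quantile defining the within-lesion habitat
#'   (default 0.5, the median).
#' @return A list of class `HabitatConfig`.
#' @export
habitatConfig <- function(sphereDiameterMM = 15, deviationK = 1,
                          connectivity = 26, medianFraction = 0.5) {
  stopifnot(sphereDiameterMM > 0, medianFraction > 0, medianFraction < 1,
            connectivity %in% c(6, 18, 26))
  structure(list(sphereDiameterMM = sphereDiameterMM,
                 deviationK = deviationK,
                 connectivity = connectivity,
                 medianFraction = medianFraction),
            class = "HabitatConfig")
}

#' Sphere habitat: low-ADC region in a fixed sphere around the lesion
#'
#' Centres a sphere of `cfg$sphereDiameterMM` diameter at the lesion's
#' geometric centroid (world mm; membership tested at voxel centres),
#' intersects it with the gland, and keeps the largest connected component
#' of voxels whose ADC is at or below `mu - k*sigma`, where `mu`/`sigma`
#' are the mean/SD of ADC over the sphere-gland intersection. If that
#' thresholded set is empty the threshold falls back to `mu`. The result
#' may extend beyond the radiologist lesion but is always inside the gland.
#'
#' @param adc the ADC [ScanVolume-class] (raw, unstandardised).
#' @param lesion the lesion [RegionMask-class].
#' @param gland the gland [RegionMask-class].
#' @param cfg a [habitatConfig()].
#' @return A [RegionMask-class] with label `"HABITAT_SPHERE"`.
#' @export
habitatSphere <- function(adc, lesion, gland, cfg = habitatConfig()) {
  stopifnot(is(adc, "ScanVolume"), is(lesion, "RegionMask"),
            is(gland, "RegionMask"))
  assertSameGrid(lesion, adc, "lesion mask")
  assertSameGrid(gland, adc, "gland mask")
  if (sum(lesion@voxels) < 1L) stop("empty lesion mask", call. = FALSE)
  if (sum(gland@voxels) < 1L) stop("empty gland mask", call. = FALSE)
  d <- dim(adc@voxels)
  les_ind <- which(lesion@voxels > 0L, arr.ind = TRUE)
  centroid <- colMeans(worldCoords(les_ind, adc@spacing, adc@origin))
  # world-mm distance of every voxel centre to the centroid
  dist2 <- outer(outer((adc@origin[1] + (seq_len(d[1]) - 1) * adc@spacing[1] - centroid[1])^2,
                       (adc@origin[2] + (seq_len(d[2]) - 1) * adc@spacing[2] - centroid[2])^2, "+"),
                 (adc@origin[3] + (seq_len(d[3]) - 1) * adc@spacing[3] - centroid[3])^2, "+")
  sphere <- dist2 <= (cfg$sphereDiameterMM / 2)^2
  search <- sphere & gland@voxels > 0L
  if (!any(search))
    stop("lesion centroid outside gland neighborhood: sphere does not intersect the gland",
         call. = FALSE)
  vals <- adc@voxels[search]
  mu <- mean(vals)
  sigma <- stats::sd(vals)
  sel <- search & adc@voxels <= mu - cfg$deviationK * sigma
  if (!any(sel))
    sel <- search & adc@voxels <= mu
  hab <- largestComponent(sel, cfg$connectivity)
  RegionMask(hab, spacing = adc@spacing, origin = adc@origin,
             label = "HABITAT_SPHERE", lesionID = lesion@lesionID)
}

#' Within-lesion habitat: contiguous at-or-below-median ADC region
#'
#' Thresholds the ADC map at the `cfg$medianFraction` quantile (default the
#' median, midpoint-interpolated; ties included) of the intensities inside
#' the lesion, and keeps the largest connected component. The result is
#' always contained in the lesion.
#'
#' @inheritParams habitatSphere
#' @return A [RegionMask-class] with label `"HABITAT_MEDIAN"`.
#' @export
habitatWithinLesion <- function(adc, lesion, cfg = habitatConfig()) {
  stopifnot(is(adc, "ScanVolume"), is(lesion, "RegionMask"))
  assertSameGrid(lesion, adc, "lesion mask")
  n_les <- sum(lesion@voxels)
  if (n_les < 1L) stop("empty lesion mask", call. = FALSE)
  if (n_les < 8L)
    stop("lesion mask must contain at least 8 voxels", call. = FALSE)
  inles <- lesion@voxels > 0L
  cutoff <- stats::quantile(adc@voxels[inles], probs = cfg$medianFraction,
                            names = FALSE, type = 7)
  sel <- inles & adc@voxels <= cutoff
  hab <- largestComponent(sel, cfg$connectivity)
  RegionMask(hab, spacing = adc@spacing, origin = adc@origin,
             label = "HABITAT_MEDIAN", lesionID = lesion@lesionID)
}
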