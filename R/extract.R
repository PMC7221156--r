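# Full 307-feature extraction for one (volume, ROI) pair.

#' Extract the full 307-feature signature for one ROI
#'
#' Computes every catalog feature on one intensity volume and one region
#' mask. Texture-matrix families are computed on a fixed-bin-number
#' quantisation (Ng levels over the in-ROI min-max range); shape features
#' are spacing-aware; filter-bank families operate on the ROI bounding box
#' with a margin. Feature values that are undefined on a degenerate ROI
#' (e.g. co-occurrence correlation of a constant region) are returned as
#' `NaN` and excluded pairwise downstream.
#'
#' @param vol a [ScanVolume-class].
#' @param roi a [RegionMask-class] with at least 2 foreground voxels.
#' @param Ng number of grey levels for discretisation (default 32).
#' @param catalog catalog data.frame, defaults to [buildCatalog()].
#' @return Named numeric vector of length 307; names are the catalog
#'   `feature_id`s in catalog order.
#' @examples
#' set.seed(1)
#' v <- ScanVolume(array(rnorm(16^3), dim = c(16, 16, 16)))
#' m <- array(0L, dim = c(16, 16, 16)); m[6:11, 6:11, 6:11] <- 1L
#' fv <- extractFeatures(v, RegionMask(m))
#' fv["F52:Vol-(mm^3)"]
#' @export
extractFeatures <- function(vol, roi, Ng = 32L, catalog = buildCatalog()) {
  stopifnot(is(vol, "ScanVolume"), is(roi, "RegionMask"))
  assertSameGrid(roi, vol, "roi mask")
  if (sum(roi@voxels) < 2L)
    stop("ROI must contain at least 2 voxels", call. = FALSE)

  # crop to the ROI bounding box plus margin to keep filtering cheap;
  # adjust the origin so world coordinates are unchanged
  bb <- maskBoundingBox(roi@voxels > 0L, margin = 4L)
  start <- vapply(bb, min, numeric(1))
  cvol <- vol
  cvol@voxels <- vol@voxels[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  cvol@origin <- vol@origin + (start - 1) * vol@spacing
  croi <- roi
  croi@voxels <- roi@voxels[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  croi@origin <- cvol@origin

  q <- quantizeROI(cvol, croi, Ng = Ng)

  by_name <- c(statFeatures(cvol, croi),
               inthistFeatures(q),
               shapeFeatures(cvol, croi),
               locintFeatures(cvol, croi),
               glcm3dFeatures(q),
               glrlm3dFeatures(q),
               glszmFeatures(q),
               ngtdmFeatures(q),
               laws3dFeatures(cvol, croi),
               wavelet3dFeatures(cvol, croi))
  stopifnot(!anyDuplicated(names(by_name)))
  missing <- setdiff(catalog$name, names(by_name))
  if (length(missing))
    stop(sprintf("internal: features not computed: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  vals <- unname(by_name[catalog$name])
  names(vals) <- catalog$feature_id
  vals
}

#' Extract features for a whole cohort into a FeatureMatrix
#'
#' Runs [extractFeatures()] for every patient-lesion, timepoint, region
#' variant and modality of a cohort (see [generatePhantomCohort()] for the
#' in-memory cohort layout) and assembles the long-format table.
#'
#' @param cohort a cohort list as produced by [generatePhantomCohort()] or
#'   [loadCohort()].
#' @param variants subset of the region variants
#'   `RADIOLOGIST_RAW, RADIOLOGIST_Z, HABITAT_SPHERE_RAW, HABITAT_SPHERE_Z,
#'   HABITAT_MEDIAN_RAW, HABITAT_MEDIAN_Z`.
#' @param modalities subset of `c("T2W", "ADC")`.
#' @param Ng grey levels for discretisation.
#' @param habitat a [habitatConfig()].
#' @param catalog feature catalog.
#' @return A [FeatureMatrix-class].
#' @export
extractCohortFeatures <- function(cohort,
                                  variants = c("RADIOLOGIST_RAW", "RADIOLOGIST_Z",
                                               "HABITAT_SPHERE_RAW", "HABITAT_SPHERE_Z"),
                                  modalities = c("T2W", "ADC"),
                                  Ng = 32L,
                                  habitat = habitatConfig(),
                                  catalog = buildCatalog()) {
  stopifnot(all(variants %in% REGION_VARIANTS))
  rows <- list()
  for (pat in cohort$patients) {
    for (tp in TIMEPOINTS) {
      scan <- pat[[tolower(tp)]]
      zvols <- list()
      need_z <- any(grepl("_Z$", variants))
      if (need_z)
        for (mod in modalities)
          zvols[[mod]] <- zscoreStandardize(scan$volumes[[mod]], pat$gland)$volume
      for (les in scan$lesions) {
        rois <- list()
        if (any(grepl("^RADIOLOGIST", variants)))
          rois[["RADIOLOGIST"]] <- les$mask
        if (any(grepl("^HABITAT_SPHERE", variants)))
          rois[["HABITAT_SPHERE"]] <- habitatSphere(scan$volumes$ADC, les$mask,
                                                    pat$gland, habitat)
        if (any(grepl("^HABITAT_MEDIAN", variants)))
          rois[["HABITAT_MEDIAN"]] <- habitatWithinLesion(scan$volumes$ADC,
                                                          les$mask, habitat)
        for (variant in variants) {
          base <- sub("_(RAW|Z)$", "", variant)
          zscored <- grepl("_Z$", variant)
          roi <- rois[[base]]
          for (mod in modalities) {
            v <- if (zscored) zvols[[mod]] else scan$volumes[[mod]]
            fv <- extractFeatures(v, roi, Ng = Ng, catalog = catalog)
            rows[[length(rows) + 1L]] <- data.frame(
              patient_id = pat$patient_id, lesion_id = les$lesion_id,
              timepoint = tp, region_variant = variant, modality = mod,
              feature_id = names(fv), value = unname(fv),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  FeatureMatrix(do.call(rbind, rows))
}
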