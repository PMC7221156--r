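#' @import methods
NULL

VOLUME_MODALITIES <- c("T2W", "ADC")
TIMEPOINTS <- c("TEST", "RETEST")
MASK_LABELS <- c("GLAND", "LESION", "HABITAT_SPHERE", "HABITAT_MEDIAN")
REGION_VARIANTS <- c("RADIOLOGIST_RAW", "RADIOLOGIST_Z",
                     "HABITAT_SPHERE_RAW", "HABITAT_SPHERE_Z",
                     "HABITAT_MEDIAN_RAW", "HABITAT_MEDIAN_Z")

#' ScanVolume: a single-modality, single-timepoint 3D image
#'
#' Holds the voxel array of one scan together with its sampling grid.
#' Intensities are in arbitrary units for T2-weighted volumes and in
#' 10^-6 mm^2/s-scaled units for apparent diffusion coefficient (ADC) maps.
#' Voxel index (1,1,1) is the first voxel; world coordinates of a voxel
#' centre are `origin + (index - 1) * spacing` (mm).
#'
#' @slot voxels 3D numeric array of intensities (finite-valued).
#' @slot spacing numeric length-3, voxel spacing (dx, dy, dz) in mm, all > 0.
#' @slot origin numeric length-3, world coordinate of the first voxel centre (mm).
#' @slot modality `"T2W"` or `"ADC"`.
#' @slot timepoint `"TEST"` or `"RETEST"`.
#' @slot patientID patient identifier.
#' @export
setClass("ScanVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 modality = "character", timepoint = "character",
                 patientID = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0),
            modality = "T2W", timepoint = "TEST", patientID = "P0"))

setValidity("ScanVolume", function(object) {
  msg <- character(0)
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "expected 3D volume")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values (mm)")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have three components (mm)")
  if (!all(is.finite(object@voxels)))
    msg <- c(msg, "voxel array contains non-finite values")
  if (!object@modality %in% VOLUME_MODALITIES)
    msg <- c(msg, sprintf("modality must be one of %s",
                          paste(VOLUME_MODALITIES, collapse = ", ")))
  if (!object@timepoint %in% TIMEPOINTS)
    msg <- c(msg, sprintf("timepoint must be one of %s",
                          paste(TIMEPOINTS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' RegionMask: a binary 3D mask on a ScanVolume's grid
#'
#' @slot voxels 3D array of 0/1 (stored as integer).
#' @slot spacing,origin grid, identical to the annotated volume.
#' @slot label one of `"GLAND"`, `"LESION"`, `"HABITAT_SPHERE"`,
#'   `"HABITAT_MEDIAN"`.
#' @slot lesionID lesion identifier ("" for gland masks).
#' @export
setClass("RegionMask",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 label = "character", lesionID = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0),
            label = "LESION", lesionID = ""))

setValidity("RegionMask", function(object) {
  msg <- character(0)
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "expected 3D mask")
  if (!all(object@voxels %in% c(0L, 1L)))
    msg <- c(msg, "mask voxels must be binary")
  if (!object@label %in% MASK_LABELS)
    msg <- c(msg, sprintf("label must be one of %s",
                          paste(MASK_LABELS, collapse = ", ")))
  if (object@label %in% c("GLAND", "LESION") && sum(object@voxels) < 1)
    msg <- c(msg, sprintf("%s mask has no foreground voxels", object@label))
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: long-format radiomic feature values
#'
#' Rows are keyed by (patient_id, lesion_id, timepoint, region_variant,
#' modality, feature_id); `value` holds the feature value. Duplicate keys
#' are rejected.
#'
#' @slot data a data.frame with the seven columns above.
#' @export
setClass("FeatureMatrix", representation(data = "data.frame"))

FM_COLUMNS <- c("patient_id", "lesion_id", "timepoint", "region_variant",
                "modality", "feature_id", "value")

setValidity("FeatureMatrix", function(object) {
  d <- object@data
  missing_cols <- setdiff(FM_COLUMNS, names(d))
  if (length(missing_cols))
    return(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")))
  key <- do.call(paste, c(d[setdiff(FM_COLUMNS, "value")], sep = "\r"))
  if (anyDuplicated(key))
    return("duplicate (patient, lesion, timepoint, variant, modality, feature) keys")
  if (!is.numeric(d$value))
    return("value column must be numeric")
  TRUE
})

# ---- constructors -----------------------------------------------------------

#' Construct a ScanVolume
#'
#' @param voxels 3D numeric array.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param origin world coordinates of the first voxel centre in mm.
#' @param modality `"T2W"` or `"ADC"`.
#' @param timepoint `"TEST"` or `"RETEST"`.
#' @param patientID patient identifier.
#' @return A [ScanVolume-class] object.
#' @export
ScanVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       modality = "T2W", timepoint = "TEST",
                       patientID = "P0") {
  new("ScanVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), modality = modality,
      timepoint = timepoint, patientID = patientID)
}

#' Construct a RegionMask
#'
#' Any nonzero voxel is treated as foreground.
#'
#' @param voxels 3D array; nonzero entries become foreground.
#' @param spacing,origin grid of the annotated volume.
#' @param label mask label.
#' @param lesionID lesion identifier (ignored for gland masks).
#' @return A [RegionMask-class] object.
#' @export
RegionMask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       label = "LESION", lesionID = "") {
  v <- array(as.integer(voxels != 0), dim = dim(voxels))
  new("RegionMask", voxels = v, spacing = as.numeric(spacing),
      origin = as.numeric(origin), label = label, lesionID = lesionID)
}

#' Construct a FeatureMatrix from a long data.frame
#'
#' @param data data.frame with columns patient_id, lesion_id, timepoint,
#'   region_variant, modality, feature_id, value.
#' @return A [FeatureMatrix-class] object.
#' @export
FeatureMatrix <- function(data) {
  rownames(data) <- NULL
  new("FeatureMatrix", data = as.data.frame(data)[FM_COLUMNS])
}

# ---- accessors --------------------------------------------------------------

#' @rdname ScanVolume
#' @param object a ScanVolume or RegionMask.
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname ScanVolume
#' @export
setMethod("voxels", "ScanVolume", function(object) object@voxels)
#' @rdname ScanVolume
#' @export
setMethod("voxels", "RegionMask", function(object) object@voxels)

#' @rdname ScanVolume
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname ScanVolume
#' @export
setMethod("voxelSpacing", "ScanVolume", function(object) object@spacing)
#' @rdname ScanVolume
#' @export
setMethod("voxelSpacing", "RegionMask", function(object) object@spacing)

#' @rdname ScanVolume
#' @export
setGeneric("worldOrigin", function(object) standardGeneric("worldOrigin"))
#' @rdname ScanVolume
#' @export
setMethod("worldOrigin", "ScanVolume", function(object) object@origin)
#' @rdname ScanVolume
#' @export
setMethod("worldOrigin", "RegionMask", function(object) object@origin)

#' @rdname ScanVolume
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))
#' @rdname ScanVolume
#' @export
setMethod("modality", "ScanVolume", function(object) object@modality)

#' @rdname ScanVolume
#' @export
setGeneric("timepoint", function(object) standardGeneric("timepoint"))
#' @rdname ScanVolume
#' @export
setMethod("timepoint", "ScanVolume", function(object) object@timepoint)

#' @rdname ScanVolume
#' @export
setGeneric("patientID", function(object) standardGeneric("patientID"))
#' @rdname ScanVolume
#' @export
setMethod("patientID", "ScanVolume", function(object) object@patientID)

#' @rdname RegionMask
#' @param object a RegionMask.
#' @export
setGeneric("maskLabel", function(object) standardGeneric("maskLabel"))
#' @rdname RegionMask
#' @export
setMethod("maskLabel", "RegionMask", function(object) object@label)

#' @rdname RegionMask
#' @export
setGeneric("lesionID", function(object) standardGeneric("lesionID"))
#' @rdname RegionMask
#' @export
setMethod("lesionID", "RegionMask", function(object) object@lesionID)

#' @rdname RegionMask
#' @export
setGeneric("foregroundCount", function(object) standardGeneric("foregroundCount"))
#' @rdname RegionMask
#' @export
setMethod("foregroundCount", "RegionMask", function(object) sum(object@voxels))

#' @rdname FeatureMatrix
#' @param object a FeatureMatrix.
#' @export
setGeneric("featureData", function(object) standardGeneric("featureData"))
#' @rdname FeatureMatrix
#' @export
setMethod("featureData", "FeatureMatrix", function(object) object@data)

#' @rdname FeatureMatrix
#' @export
setGeneric("featureIDs", function(object) standardGeneric("featureIDs"))
#' @rdname FeatureMatrix
#' @export
setMethod("featureIDs", "FeatureMatrix",
          function(object) unique(object@data$feature_id))

# ---- show -------------------------------------------------------------------

setMethod("show", "ScanVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ScanVolume %s/%s patient=%s\n  dims %d x %d x %d, spacing (%g, %g, %g) mm\n  intensity range [%.4g, %.4g]\n",
              object@modality, object@timepoint, object@patientID,
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3],
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "RegionMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("RegionMask %s%s\n  dims %d x %d x %d, %d foreground voxels\n",
              object@label,
              if (nzchar(object@lesionID)) paste0(" lesion=", object@lesionID) else "",
              d[1], d[2], d[3], sum(object@voxels)))
})

setMethod("show", "FeatureMatrix", function(object) {
  d <- object@data
  cat(sprintf("FeatureMatrix: %d rows, %d features, %d patient-lesions\n",
              nrow(d), length(unique(d$feature_id)),
              length(unique(paste(d$patient_id, d$lesion_id)))))
  cat(sprintf("  variants: %s\n  modalities: %s\n",
              paste(unique(d$region_variant), collapse = ", "),
              paste(unique(d$modality), collapse = ", ")))
})

# ---- grid helpers -----------------------------------------------------------

# Grid compatibility: same shape, spacing within 1e-3 mm, origin within
# 1e-2 mm (strict equality is brittle across NIfTI writers).
sameGrid <- function(a, b, spacing_tol = 1e-3, origin_tol = 1e-2) {
  identical(dim(a@voxels), dim(b@voxels)) &&
    all(abs(a@spacing - b@spacing) <= spacing_tol) &&
    all(abs(a@origin - b@origin) <= origin_tol)
}

assertSameGrid <- function(mask, vol, what = "mask") {
  if (!sameGrid(mask, vol))
    stop(sprintf("grid mismatch: %s shape/spacing/origin differs from reference volume", what),
         call. = FALSE)
  invisible(TRUE)
}
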