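# NIfTI volume/mask I/O and feature-table serialisation.
#
# Volumes and masks are exchanged as NIfTI-1 (.nii / .nii.gz); the sampling
# grid is carried in pixdim (spacing, mm) and the qform translation
# (origin, mm). Feature tables are long-format CSV (UTF-8, header row,
# '.' decimal) that round-trip at 12 significant digits.

#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param modality `"T2W"` or `"ADC"`.
#' @param timepoint `"TEST"` or `"RETEST"`.
#' @param patientID patient identifier recorded on the returned object.
#' @return A [ScanVolume-class] with spacing/origin taken from the header.
#' @export
readVolume <- function(path, modality = "T2W", timepoint = "TEST",
                       patientID = "P0") {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L)
    a <- array(a, dim = dim(a)[1:3])
  if (length(dim(a)) != 3L)
    stop(sprintf("expected 3D volume: %s has %d dimensions",
                 path, length(dim(a))), call. = FALSE)
  if (!all(is.finite(a)))
    stop(sprintf("volume contains NaN/Inf voxels: %s", path), call. = FALSE)
  sp <- abs(RNifti::pixdim(img)[1:3])
  org <- RNifti::xform(img)[1:3, 4]
  ScanVolume(a, spacing = sp, origin = as.numeric(org), modality = modality,
             timepoint = timepoint, patientID = patientID)
}

#' Write a ScanVolume or RegionMask to NIfTI
#'
#' Habitat masks are written with label codes 2 (sphere) and 3 (within-lesion
#' sub-median); gland and lesion masks with 1.
#'
#' @param object a [ScanVolume-class] or [RegionMask-class].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(object, path) {
  a <- object@voxels
  if (is(object, "RegionMask")) {
    code <- switch(object@label, HABITAT_SPHERE = 2L, HABITAT_MEDIAN = 3L, 1L)
    a <- array(as.integer(a) * code, dim = dim(a))
  }
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- object@spacing
  m <- diag(4)
  diag(m)[1:3] <- object@spacing
  m[1:3, 4] <- object@origin
  RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary region mask on a reference volume's grid
#'
#' Any nonzero voxel is treated as foreground. The mask must live on the
#' same grid as `reference`: identical shape, spacing within 1e-3 mm and
#' origin within 1e-2 mm.
#'
#' @param path path to a NIfTI mask.
#' @param reference the [ScanVolume-class] the mask annotates.
#' @param label mask label (`"GLAND"`, `"LESION"`, `"HABITAT_SPHERE"`,
#'   `"HABITAT_MEDIAN"`).
#' @param lesionID lesion identifier.
#' @return A [RegionMask-class].
#' @export
readMask <- function(path, reference, label = "LESION", lesionID = "") {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L)
    a <- array(a, dim = dim(a)[1:3])
  if (length(dim(a)) != 3L)
    stop(sprintf("expected 3D mask: %s", path), call. = FALSE)
  sp <- abs(RNifti::pixdim(img)[1:3])
  org <- as.numeric(RNifti::xform(img)[1:3, 4])
  mask <- RegionMask(a, spacing = sp, origin = org, label = label,
                     lesionID = lesionID)
  assertSameGrid(mask, reference, what = basename(path))
  if (label %in% c("GLAND", "LESION") && sum(mask@voxels) < 1)
    stop(sprintf("empty %s mask: %s", label, path), call. = FALSE)
  mask
}

#' Write a FeatureMatrix to long-format CSV
#'
#' Columns: patient_id, lesion_id, timepoint, region_variant, modality,
#' feature_id, value. Values are serialised at 12 significant digits so the
#' table round-trips losslessly at that precision.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
  stopifnot(is(fm, "FeatureMatrix"))
  d <- fm@data
  if (!nrow(d)) stop("empty feature matrix", call. = FALSE)
  out <- d
  out$value <- formatC(d$value, digits = 12, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = 1:6,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a FeatureMatrix from CSV
#'
#' @param path CSV produced by [writeFeatureMatrix()].
#' @return A [FeatureMatrix-class].
#' @export
readFeatureMatrix <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character",
                                      lesion_id = "character",
                                      timepoint = "character",
                                      region_variant = "character",
                                      modality = "character",
                                      feature_id = "character",
                                      value = "numeric"),
                       fileEncoding = "UTF-8")
  FeatureMatrix(d)
}
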