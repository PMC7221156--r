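# The 307-feature catalog.
#
# Features are indexed F1..F307 and fall into three broad categories:
#   C1 - size and shape (45 features),
#   C2 - intensity statistics, intensity histogram, local intensity, and
#        the co-occurrence / run-length / size-zone / grey-tone difference
#        texture-matrix families (107 features),
#   C3 - Laws and wavelet filter-bank textures (155 features).
# Roughly fifty (index, name) pairs are fixed by the published feature
# lists this catalog mirrors (e.g. F148:NGTDM_Coarseness,
# F54:Surface-area-(mm^2), F228:3D-LawsF-R5-L5-L5); the remaining
# membership is this package's published convention. Histogram features
# that are constants by construction under fixed-bin-number min-max
# discretisation (minimum/maximum level, level range) are deliberately
# excluded: they carry no cohort information and have zero dynamic range.

LAWS_KERNELS <- list(
  L5 = c(1, 4, 6, 4, 1),       # level
  E5 = c(-1, -2, 0, 2, 1),     # edge
  S5 = c(-1, 0, 2, 0, -1),     # spot
  R5 = c(1, -4, 6, -4, 1),     # ripple
  W5 = c(-1, 2, 0, -2, 1))     # wave

STAT_NAMES <- c(
  "Stat-Mean", "Stat-Var", "Stat-SD", "Stat-Skewness", "Stat-Kurtosis",
  "Stat-Median", "Stat-Min-gray-level", "Stat-10th-percentile",
  "Stat-90th-percentile", "Stat-Max-gray-level", "Stat-75th-percentile",
  "Stat-range", "Stat-Interquartile-range", "Stat-Mean-abs-dev",
  "Stat-Robust-mean-abs-dev", "Stat-Median-abs-dev",
  "Stat-Coeff-of-variation", "Stat-ENERGY", "Stat-Root-Mn-Sq")

INTHIST_NAMES <- c(
  "Int-hist-mean", "Int-hist-var", "Int-hist-skewness", "Int-hist-kurtosis",
  "Int-hist-median", "Int-hist-10th-percentile", "Int-hist-25th-percentile",
  "Int-hist-90th-percentile", "Int-hist-75th-percentile", "Int-hist-mode",
  "Int-hist-interquartile-range", "Int-hist-mean-abs-dev",
  "Int-hist-robust-mean-abs-dev", "Int-hist-median-abs-dev",
  "Int-hist-coeff-of-variation", "Int-hist-quartile-coeff-dispersion",
  "Int-hist-entropy", "Int-hist-uniformity", "Int-hist-mode-fraction",
  "Max-hist-Gradient", "Max-hist-Gradient-gray-level",
  "Min-hist-Gradient", "Min-hist-Gradient-gray-level")

SHAPE_NAMES_A <- c(  # F43..F81
  "Vol-at-Int-Fraction-10", "Vol-at-Int-Fraction-20", "Vol-at-Int-Fraction-30",
  "Vol-at-Int-Fraction-40", "Vol-at-Int-fraction-diff",
  "Vol-at-Int-Fraction-50", "Vol-at-Int-Fraction-60", "Vol-at-Int-Fraction-70",
  "Vol-at-Int-Fraction-90",
  "Vol-(mm^3)", "Vol-voxel-count", "Surface-area-(mm^2)",
  "Surface-to-vol-ratio-(1/mm)", "Sphericity", "Compactness-1",
  "Compactness-2", "Spherical-disproportion", "Max-3D-diameter-(mm)",
  "Major-axis-length-(mm)", "Minor-axis-length-(mm)", "Least-axis-length-(mm)",
  "Elongation", "Flatness", "BBox-dim-x-(mm)", "BBox-dim-y-(mm)",
  "BBox-dim-z-(mm)", "BBox-vol-(mm^3)", "Extent", "Num-slices",
  "Max-slice-area-(mm^2)", "Mean-slice-area-(mm^2)",
  "Equiv-sphere-diameter-(mm)", "Equiv-sphere-surface-(mm^2)", "Asphericity",
  "Centroid-x-(mm)", "Centroid-y-(mm)", "Centroid-z-(mm)",
  "Radial-mean-(mm)", "Radial-SD-(mm)")

SHAPE_NAMES_B <- c(  # F85..F90
  "Weighted-CoM_x-(mm)", "Weighted-CoM_y-(mm)", "Weighted-CoM_z-(mm)",
  "Center-of-mass-shift-(mm)", "Border-length-max-slice-(mm)",
  "Border-length-(mm)")

LOCINT_NAMES_A <- c(  # F82..F84
  "LocInt-Peak-local-mean", "LocInt-Max-local-mean", "LocInt-Min-local-mean")
LOCINT_NAMES_B <- c(  # F91..F92
  "LocInt-Mean-local-var", "LocInt-Mean-local-range")

GLCM_NAMES <- paste0("avgCooc_3D_", c(
  "Joint-var", "Joint-avg", "Joint-entropy", "Difference-var",
  "Difference-entropy", "Difference-avg", "Sum-var", "Sum-entropy",
  "Sum-avg", "Angular-second-moment", "Contrast", "Dissimilarity",
  "Inv-diff", "Inv-diff-mom", "Inv-diff-mom-norm", "Inverse-variance",
  "Correlation", "Autocorrelation", "Cluster-tendency", "Cluster-shade",
  "Cluster-prominence", "First-measure-of-information-correlation",
  "Second-measure-of-information-correlation"))

GLRLM_NAMES <- paste0("avg_3D_", c(
  "SRE-(Short-runs-emphasis)", "LRE-(Long-runs-emphasis)",
  "LGRE-(Low-gray-level-run-emphasis)", "HGRE-(High-gray-level-run-emphasis)",
  "SRLGE-(Short-run-low-gray-level-emphasis)",
  "SRHGE-(Short-run-high-gray-level-emphasis)",
  "LRLGE-(Long-run-low-gray-level-emphasis)",
  "LRHGE-(Long-run-high-gray-level-emphasis)",
  "GLN-(Gray-level-non-uniformity)",
  "GLNN-(Gray-level-non-uniformity-normalized)",
  "RLN-(Run-length-non-uniformity)",
  "RLNN-(Run-length-non-uniformity-normalized)",
  "RP-(Run-percentage)", "GLV-(Gray-level-variance)",
  "RLV-(Run-length-variance)", "RE-(Run-entropy)"))

GLSZM_NAMES <- paste0("GLSZM_", c(
  "Small-zone-emphasis", "Large-zone-emphasis", "Low-gray-level-zone-emphasis",
  "High-gray-level-zone-emphasis", "Small-zone-low-gray-level-emphasis",
  "Small-zone-high-gray-level-emphasis", "Large-zone-low-gray-level-emphasis",
  "Large-zone-high-gray-level-emphasis", "Gray-level-non-uniformity",
  "Gray-level-non-uniformity-normalized", "Zone-size-non-uniformity",
  "Zone-size-non-uniformity-normalized", "Zone-percentage",
  "Gray-level-variance", "Zone-size-variance", "Zone-size-entropy"))

NGTDM_NAMES <- paste0("NGTDM_", c(
  "Coarseness", "Contrast", "Busyness", "Complexity", "Strength"))

#' Build the ordered 307-feature catalog
#'
#' Returns the full feature catalog: 45 size/shape features (category C1),
#' 107 intensity/histogram/texture-matrix features (C2), and 155 Laws and
#' wavelet filter-bank features (C3). Feature identifiers have the form
#' `"F<k>:<name>"` with k = 1..307.
#'
#' @return A data.frame with columns `index`, `feature_id`, `name`,
#'   `family` (STAT, INTHIST, SHAPE, LOCINT, GLCM3D, GLRLM3D, GLSZM, NGTDM,
#'   LAWS3D, WAVELET3D), `category` (C1/C2/C3) and `params` (kernel triple
#'   or subband code where applicable, otherwise "").
#' @examples
#' cat307 <- buildCatalog()
#' nrow(cat307)
#' table(cat307$category)
#' @export
buildCatalog <- function() {
  kn <- names(LAWS_KERNELS)
  laws_triples <- as.matrix(expand.grid(k3 = kn, k2 = kn, k1 = kn,
                                        stringsAsFactors = FALSE))[, 3:1]
  laws_names <- apply(laws_triples, 1L, function(r)
    paste0("3D-LawsF-", r[1], "-", r[2], "-", r[3]))
  laws_params <- apply(laws_triples, 1L, paste, collapse = ",")

  wave_names <- as.vector(rbind(paste0("3D-Wave-P1-L2-C", 1:15),
                                paste0("3D-Wave-P1-L2-C", 1:15, "-energy")))
  wave_params <- as.vector(rbind(paste0("C", 1:15, ":mean-abs"),
                                 paste0("C", 1:15, ":energy")))

  blocks <- list(
    list(STAT_NAMES, "STAT", "C2", ""),
    list(INTHIST_NAMES, "INTHIST", "C2", ""),
    list(SHAPE_NAMES_A, "SHAPE", "C1", ""),
    list(LOCINT_NAMES_A, "LOCINT", "C2", ""),
    list(SHAPE_NAMES_B, "SHAPE", "C1", ""),
    list(LOCINT_NAMES_B, "LOCINT", "C2", ""),
    list(GLCM_NAMES, "GLCM3D", "C2", ""),
    list(GLRLM_NAMES, "GLRLM3D", "C2", ""),
    list(GLSZM_NAMES, "GLSZM", "C2", ""),
    list(NGTDM_NAMES, "NGTDM", "C2", ""),
    list(laws_names, "LAWS3D", "C3", laws_params),
    list(wave_names, "WAVELET3D", "C3", wave_params))

  name <- unlist(lapply(blocks, `[[`, 1L))
  family <- unlist(lapply(blocks, function(b) rep(b[[2]], length(b[[1]]))))
  category <- unlist(lapply(blocks, function(b) rep(b[[3]], length(b[[1]]))))
  params <- unlist(lapply(blocks, function(b) {
    p <- b[[4]]
    if (length(p) == 1L && !nzchar(p[1L])) rep("", length(b[[1]])) else p
  }))
  stopifnot(length(name) == 307L)
  data.frame(index = seq_len(307L),
             feature_id = paste0("F", seq_len(307L), ":", name),
             name = name, family = family, category = category,
             params = params, stringsAsFactors = FALSE)
}

#' Export the feature catalog as JSON
#'
#' @param path output path; the JSON is an array of 307 objects with fields
#'   feature_id, family, category and params.
#' @param catalog catalog data.frame, defaults to [buildCatalog()].
#' @return `path`, invisibly.
#' @export
writeCatalogJSON <- function(path, catalog = buildCatalog()) {
  jsonlite::write_json(
    catalog[c("feature_id", "family", "category", "params")],
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# catalog index from a feature_id like "F126:avg_3D_RLN-..."; NA for ids
# outside the F<k>:<name> convention
catalogIndex <- function(feature_id) {
  suppressWarnings(as.integer(sub("^F([0-9]+):.*$", "\\1", feature_id)))
}
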