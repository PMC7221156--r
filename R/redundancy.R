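# Redundancy reduction: recursive grouping of reproducible features by
# coefficient of determination (R^2), keeping in each group the
# representative with the highest dynamic range.

#' Coefficient of determination between two feature vectors
#'
#' The squared Pearson correlation. If either vector is constant no linear
#' dependence is estimable and 0 is returned, so constant features are
#' never grouped with anything.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return R^2 in `[0, 1]`.
#' @export
rsq <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("rsq requires at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Redundancy configuration
#'
#' @param rsqCutoff R^2 at or above which two features are considered
#'   redundant; defaults in the pipeline are run at 0.99 and 0.95.
#' @return list of class `RedundancyConfig`. Test and retest values are
#'   always averaged per subject before R^2 is computed (fixed rule).
#' @export
redundancyConfig <- function(rsqCutoff = 0.99) {
  stopifnot(rsqCutoff > 0, rsqCutoff <= 1)
  structure(list(rsqCutoff = rsqCutoff,
                 averaging = "mean of test and retest per subject"),
            class = "RedundancyConfig")
}

# subject x feature matrix of (test + retest)/2 averages for one
# variant/modality slice of a FeatureMatrix
subjectAverages <- function(fm, region_variant, modality, feature_ids) {
  d <- fm@data
  d <- d[d$region_variant == region_variant & d$modality == modality &
           d$feature_id %in% feature_ids, ]
  subj <- paste(d$patient_id, d$lesion_id, sep = "|")
  subjects <- unique(subj)
  mat <- matrix(NA_real_, length(subjects), length(feature_ids),
                dimnames = list(subjects, feature_ids))
  for (tp in TIMEPOINTS) {
    sel <- d$timepoint == tp
    mat_tp <- mat
    mat_tp[cbind(match(subj[sel], subjects),
                 match(d$feature_id[sel], feature_ids))] <- d$value[sel]
    if (tp == "TEST") test_m <- mat_tp else retest_m <- mat_tp
  }
  (test_m + retest_m) / 2
}

#' Greedy recursive redundancy reduction
#'
#' Given repeatability records (feature_id, dr) for the features that
#' survived the CCC/DR screen, and their subject-averaged values, selects
#' representatives: repeatedly pick the surviving feature with the highest
#' DR (ties broken to the lowest catalog index), remove every other feature
#' with `R^2 >= rsqCutoff` against it, and recurse on the remainder. Every
#' removed feature has R^2 at or above the cutoff with at least one
#' selected representative; the procedure eliminates redundancy but does
#' not certify pairwise independence of the survivors.
#'
#' @param records data.frame with at least columns `feature_id` and `dr`
#'   (e.g. a filtered [screenFeatures()] table for one variant/modality).
#' @param averages subject x feature numeric matrix of per-subject
#'   test/retest averages, with all of `records$feature_id` as columns.
#' @param cfg a [redundancyConfig()].
#' @return Character vector of selected feature_ids in selection order.
#' @examples
#' avg <- cbind(A = c(1, 2, 3, 4), B = c(1.01, 2.02, 3.02, 4.01),
#'              C = c(4, 1, 3, 2))
#' rec <- data.frame(feature_id = c("A", "B", "C"), dr = c(0.7, 0.9, 0.8))
#' reduceFeatures(rec, avg, redundancyConfig(0.99))  # B then C
#' @export
reduceFeatures <- function(records, averages, cfg = redundancyConfig()) {
  stopifnot(all(c("feature_id", "dr") %in% names(records)))
  if (!nrow(records)) return(character(0))
  stopifnot(all(records$feature_id %in% colnames(averages)))
  idx <- catalogIndex(records$feature_id)
  if (anyNA(idx)) idx <- seq_len(nrow(records))  # non-catalog ids: input order
  remaining <- order(-records$dr, idx)  # DR descending, catalog index ascending
  selected <- character(0)
  while (length(remaining)) {
    pick <- remaining[1L]
    pick_id <- records$feature_id[pick]
    selected <- c(selected, pick_id)
    remaining <- remaining[-1L]
    if (!length(remaining)) break
    keep <- vapply(remaining, function(r) {
      rsq(averages[, pick_id], averages[, records$feature_id[r]]) < cfg$rsqCutoff
    }, logical(1))
    remaining <- remaining[keep]
  }
  selected
}
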