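# Test-retest repeatability statistics: Lin's concordance correlation
# coefficient (CCC) and the normalised dynamic range (DR), plus the joint
# cutoff screen over a FeatureMatrix.

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments. Measures agreement with the identity line between paired
#' test and retest values: it penalises both poor correlation and location/
#' scale shift. Conventions: two constant and equal vectors give 1; constant
#' and unequal give 0. Pairs containing `NA`/`NaN` are dropped.
#'
#' @param test,retest paired numeric vectors.
#' @return CCC in `[-1, 1]`.
#' @examples
#' ccc(c(1, 2, 3, 4), c(2, 3, 4, 5))  # 0.7142857...
#' @export
ccc <- function(test, retest) {
  stopifnot(length(test) == length(retest))
  ok <- is.finite(test) & is.finite(retest)
  x <- test[ok]; y <- retest[ok]
  n <- length(x)
  if (n < 3L) stop("ccc requires at least 3 complete pairs", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  den <- sx2 + sy2 + (mx - my)^2
  if (den == 0) return(1)  # constant and equal
  2 * sxy / den
}

#' Normalised dynamic range of a paired feature
#'
#' `DR = 1 - mean(|test - retest|) / (Max - Min)` where Max/Min are taken
#' over the pooled test and retest values (the observed biological range of
#' the feature in the cohort). Values near 1 mean the repeat error is small
#' relative to the interpatient spread. Clipped to `[0, 1]`; a degenerate
#' pooled range (Max == Min) gives 0. Pairs containing `NA` are dropped.
#'
#' @param test,retest paired numeric vectors (>= 2 complete pairs).
#' @return DR in `[0, 1]`.
#' @examples
#' dynamicRange(c(0, 10), c(2, 8))  # 0.8
#' @export
dynamicRange <- function(test, retest) {
  stopifnot(length(test) == length(retest))
  ok <- is.finite(test) & is.finite(retest)
  x <- test[ok]; y <- retest[ok]
  if (length(x) < 2L)
    stop("dynamicRange requires at least 2 complete pairs", call. = FALSE)
  pooled_range <- max(x, y) - min(x, y)
  if (pooled_range == 0) return(0)
  dr <- 1 - mean(abs(x - y)) / pooled_range
  min(max(dr, 0), 1)
}

#' Screen features by joint CCC and DR cutoffs
#'
#' For every (region_variant, modality, feature_id) of a feature matrix
#' containing both timepoints, aligns the patient-lesion pairs, computes
#' CCC and DR over complete pairs, and flags passes at each cutoff with the
#' joint rule `pass(c) <=> ccc >= c & dr >= c` (the same threshold is
#' applied to both statistics). Features with fewer than 3 complete pairs
#' get `NaN` statistics and never pass (a warning lists them).
#'
#' @param fm a [FeatureMatrix-class] with both `TEST` and `RETEST` rows.
#' @param cutoffs joint cutoffs (default `seq(0.65, 0.95, by = 0.05)`).
#' @return A data.frame with columns region_variant, modality, feature_id,
#'   n_pairs, ccc, dr and one logical `pass_<c>` column per cutoff.
#' @export
screenFeatures <- function(fm, cutoffs = seq(0.65, 0.95, by = 0.05)) {
  stopifnot(is(fm, "FeatureMatrix"), length(cutoffs) >= 1)
  d <- fm@data
  if (!all(TIMEPOINTS %in% unique(d$timepoint)))
    stop("feature matrix must contain both TEST and RETEST rows", call. = FALSE)
  subject <- paste(d$patient_id, d$lesion_id, sep = "|")
  grp <- interaction(d$region_variant, d$modality, d$feature_id,
                     drop = TRUE, sep = "\r")
  pieces <- split(seq_len(nrow(d)), grp)
  out <- vector("list", length(pieces))
  low_n <- character(0)
  for (k in seq_along(pieces)) {
    rows <- pieces[[k]]
    dd <- d[rows, ]
    subj <- unique(subject[rows])
    tv <- dd$value[match(paste(subj, "TEST"),
                         paste(subject[rows], dd$timepoint))]
    rv <- dd$value[match(paste(subj, "RETEST"),
                         paste(subject[rows], dd$timepoint))]
    ok <- is.finite(tv) & is.finite(rv)
    n_pairs <- sum(ok)
    if (n_pairs >= 3L) {
      cval <- ccc(tv[ok], rv[ok])
      dval <- dynamicRange(tv[ok], rv[ok])
    } else {
      cval <- NaN; dval <- NaN
      low_n <- c(low_n, dd$feature_id[1])
    }
    rec <- data.frame(region_variant = dd$region_variant[1],
                      modality = dd$modality[1],
                      feature_id = dd$feature_id[1],
                      n_pairs = n_pairs, ccc = cval, dr = dval,
                      stringsAsFactors = FALSE)
    for (co in cutoffs)
      rec[[sprintf("pass_%.2f", co)]] <-
        is.finite(cval) && is.finite(dval) && cval >= co && dval >= co
    out[[k]] <- rec
  }
  if (length(low_n))
    warning(sprintf("%d feature(s) had < 3 complete pairs and were excluded from counts (e.g. %s)",
                    length(low_n), utils::head(low_n, 1)))
  res <- do.call(rbind, out)
  res <- res[order(res$region_variant, res$modality,
                   catalogIndex(res$feature_id)), ]
  rownames(res) <- NULL
  attr(res, "cutoffs") <- cutoffs
  res
}
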