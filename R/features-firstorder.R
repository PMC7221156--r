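# First-order intensity statistics, intensity-histogram statistics on the
# discretised grey levels, and local-intensity summaries.

popVar <- function(x) mean((x - mean(x))^2)

#' First-order intensity statistics (19 features)
#'
#' Computed on the raw in-ROI intensities. Percentiles use linear
#' interpolation (R quantile type 7); variance/SD are population moments;
#' kurtosis is excess kurtosis. The coefficient of variation is `NaN` when
#' the ROI mean is exactly zero (flagged downstream).
#'
#' @param vol a [ScanVolume-class].
#' @param roi a [RegionMask-class] with at least 2 foreground voxels.
#' @return Named numeric vector of the 19 STAT features.
#' @export
statFeatures <- function(vol, roi) {
  assertSameGrid(roi, vol, "roi mask")
  x <- vol@voxels[roi@voxels > 0L]
  if (length(x) < 2L) stop("ROI must contain at least 2 voxels", call. = FALSE)
  mu <- mean(x)
  m2 <- popVar(x)
  s <- sqrt(m2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  med <- stats::median(x)
  inner <- x[x >= q[1] & x <= q[4]]
  vals <- c(
    mu, m2, s,
    if (m2 > 0) m3 / m2^1.5 else 0,
    if (m2 > 0) m4 / m2^2 - 3 else 0,
    med, min(x), q[1], q[4], max(x), q[3],
    max(x) - min(x), q[3] - q[2],
    mean(abs(x - mu)),
    mean(abs(inner - mean(inner))),
    mean(abs(x - med)),
    if (mu != 0) s / mu else NaN,
    sum(x^2),
    sqrt(mean(x^2)))
  names(vals) <- STAT_NAMES
  vals
}

#' Intensity-histogram statistics on discretised grey levels (23 features)
#'
#' Computed on the grey levels 1..Ng of a quantised ROI. Histogram-gradient
#' features use the discrete first difference `g(k) = h(k+1) - h(k)`
#' located at level `k + 1` (ties resolved to the lowest level).
#'
#' @param q a `QuantizedROI` from [quantizeROI()].
#' @return Named numeric vector of the 23 INTHIST features.
#' @export
inthistFeatures <- function(q) {
  lev <- q$levels[q$mask]
  Ng <- q$Ng
  n <- length(lev)
  h <- tabulate(lev, nbins = Ng)
  p <- h / n
  mu <- mean(lev)
  m2 <- popVar(lev)
  s <- sqrt(m2)
  m3 <- mean((lev - mu)^3)
  m4 <- mean((lev - mu)^4)
  qq <- stats::quantile(lev, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  med <- stats::median(lev)
  inner <- lev[lev >= qq[1] & lev <= qq[4]]
  mode_level <- which.max(h)  # lowest level on ties
  grad <- diff(h)             # g(k) = h(k+1) - h(k), k = 1..Ng-1
  if (length(grad)) {
    gmax <- max(grad); gmax_at <- which.max(grad) + 1L
    gmin <- min(grad); gmin_at <- which.min(grad) + 1L
  } else {
    gmax <- 0; gmax_at <- 1L; gmin <- 0; gmin_at <- 1L
  }
  pn <- p[p > 0]
  vals <- c(
    mu, m2,
    if (m2 > 0) m3 / m2^1.5 else 0,
    if (m2 > 0) m4 / m2^2 - 3 else 0,
    med, qq[1], qq[2], qq[4], qq[3],
    mode_level,
    qq[3] - qq[2],
    mean(abs(lev - mu)),
    mean(abs(inner - mean(inner))),
    mean(abs(lev - med)),
    s / mu,
    if (qq[3] + qq[2] != 0) (qq[3] - qq[2]) / (qq[3] + qq[2]) else 0,
    -sum(pn * log2(pn)),
    sum(p^2),
    max(h) / n,
    gmax, gmax_at, gmin, gmin_at)
  names(vals) <- INTHIST_NAMES
  vals
}

# Local-intensity summaries: statistics of the 3x3x3 in-ROI neighbourhood
# (centre included) around every ROI voxel.
locintFeatures <- function(vol, roi) {
  v <- vol@voxels
  inroi <- roi@voxels > 0L
  d <- dim(v)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  acc_sum <- array(0, d); acc_sq <- array(0, d); acc_n <- array(0, d)
  acc_max <- array(-Inf, d); acc_min <- array(Inf, d)
  vin <- v; vin[!inroi] <- NA_real_
  for (r in seq_len(nrow(offs))) {
    sh <- shiftArray(vin, offs[r, ])
    ok <- !is.na(sh)
    acc_sum[ok] <- acc_sum[ok] + sh[ok]
    acc_sq[ok] <- acc_sq[ok] + sh[ok]^2
    acc_n[ok] <- acc_n[ok] + 1
    acc_max[ok] <- pmax(acc_max[ok], sh[ok])
    acc_min[ok] <- pmin(acc_min[ok], sh[ok])
  }
  m <- acc_sum / acc_n
  lvar <- acc_sq / acc_n - m^2
  lrange <- acc_max - acc_min
  roi_idx <- which(inroi)
  peak_at <- roi_idx[which.max(v[roi_idx])]  # smallest linear index on ties
  vals <- c(m[peak_at],
            max(m[roi_idx]), min(m[roi_idx]),
            mean(pmax(lvar[roi_idx], 0)), mean(lrange[roi_idx]))
  names(vals) <- c(LOCINT_NAMES_A, LOCINT_NAMES_B)
  vals
}
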