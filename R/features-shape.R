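# Size and shape features (category C1, 45 features).
#
# Shape features are spacing-aware: volumes in mm^3, areas in mm^2,
# lengths in mm, all computed in world coordinates
# (origin + (index-1) * spacing at voxel centres).

#' Size and shape features (45 features)
#'
#' Includes the volume-at-intensity-fraction curve VIF(x) = fraction of ROI
#' voxels with intensity strictly above `min + x * range` (with
#' `Vol-at-Int-fraction-diff = VIF(10%) - VIF(90%)`), mesh-free surface
#' area by exposed-face counting, in-plane border length, principal-axis
#' geometry from the voxel-coordinate covariance (axis length = 4 sqrt of
#' the eigenvalue), and geometric vs intensity-weighted centroids (weights
#' are intensities shifted to be non-negative, so a uniform ROI has zero
#' centre-of-mass shift).
#'
#' @param vol a [ScanVolume-class].
#' @param roi a [RegionMask-class] with at least 1 foreground voxel.
#' @return Named numeric vector of the 45 SHAPE features.
#' @export
shapeFeatures <- function(vol, roi) {
  assertSameGrid(roi, vol, "roi mask")
  m <- roi@voxels > 0L
  n <- sum(m)
  if (n < 1L) stop("empty ROI", call. = FALSE)
  sp <- roi@spacing
  d <- dim(m)
  voxvol <- prod(sp)
  x <- vol@voxels[m]

  # volume-at-intensity-fraction curve
  rng <- max(x) - min(x)
  vif <- function(f) if (rng > 0) mean(x > min(x) + f * rng) else 0
  vifs <- vapply(c(.1, .2, .3, .4, .5, .6, .7, .9), vif, numeric(1))

  V <- n * voxvol

  # surface area: exposed faces against background or the array boundary
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  mask_num <- array(as.numeric(m), dim = d)
  A <- 0
  exposed <- array(FALSE, dim = d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    off <- c(0L, 0L, 0L); off[ax] <- s
    nb <- shiftArray(mask_num, off, fill = 0)
    open_face <- m & nb == 0
    A <- A + sum(open_face) * face_area[ax]
    exposed <- exposed | open_face
  }

  ind <- which(m, arr.ind = TRUE)
  w <- worldCoords(ind, sp, roi@origin)

  # maximum 3D diameter over surface voxels
  surf <- which(exposed[m])
  ws <- w[surf, , drop = FALSE]
  max_diam <- if (nrow(ws) > 1L) {
    sqrt(max(stats::dist(ws)^2))
  } else 0

  # principal axes of the voxel-centre point cloud (population covariance)
  if (n > 1L) {
    cv <- stats::cov(w) * (n - 1) / n
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  axis_len <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  bbox_vox <- apply(ind, 2L, function(i) max(i) - min(i) + 1L)
  bbox_mm <- bbox_vox * sp
  bbox_vol <- prod(bbox_mm)

  slices <- table(ind[, 3])
  slice_areas <- as.numeric(slices) * sp[1] * sp[2]

  eq_d <- 2 * (3 * V / (4 * pi))^(1 / 3)

  centroid <- colMeans(w)
  rad <- sqrt(rowSums(sweep(w, 2L, centroid)^2))

  wt <- x - min(x)
  if (sum(wt) > 0) {
    wcom <- colSums(w * wt) / sum(wt)
  } else wcom <- centroid
  com_shift <- sqrt(sum((wcom - centroid)^2))

  # in-plane border length: exposed x/y edges per axial slice
  per_slice <- vapply(sort(unique(ind[, 3])), function(k) {
    sl <- m[, , k, drop = TRUE]
    dim(sl) <- d[1:2]
    e <- 0
    for (ax in 1:2) for (s in c(-1L, 1L)) {
      off3 <- c(0L, 0L, 0L); off3[ax] <- s
      sl3 <- array(sl, dim = c(d[1:2], 1L))
      nb <- shiftArray(array(as.numeric(sl3), dim = dim(sl3)), off3, fill = 0)
      e <- e + sum(sl3 & nb == 0) * sp[3 - ax]
    }
    e
  }, numeric(1))

  vals <- c(
    vifs[1], vifs[2], vifs[3], vifs[4],
    vifs[1] - vifs[8],                      # VIF(10%) - VIF(90%)
    vifs[5], vifs[6], vifs[7], vifs[8],
    V, n, A,
    A / V,
    (36 * pi * V^2)^(1 / 3) / A,
    V / (sqrt(pi) * A^1.5),
    36 * pi * V^2 / A^3,
    A / (36 * pi * V^2)^(1 / 3),
    max_diam,
    axis_len[1], axis_len[2], axis_len[3],
    elong, flat,
    bbox_mm[1], bbox_mm[2], bbox_mm[3], bbox_vol,
    V / bbox_vol,
    length(slices),
    max(slice_areas), mean(slice_areas),
    eq_d, pi * eq_d^2,
    (A^3 / (36 * pi * V^2))^(1 / 3) - 1,
    centroid[1], centroid[2], centroid[3],
    mean(rad), sqrt(popVar(rad)),
    wcom[1], wcom[2], wcom[3],
    com_shift,
    max(per_slice), sum(per_slice))
  names(vals) <- c(SHAPE_NAMES_A, SHAPE_NAMES_B)
  vals
}
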