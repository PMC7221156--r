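# Grey-level texture-matrix features on the quantised ROI.
#
# GLCM and GLRLM are computed per direction over the 13 unique 3D lattice
# directions at Chebyshev distance 1 and feature values are AVERAGED over
# directions (the "avgCooc_3D"/"avg_3D" convention); GLSZM uses a single
# matrix with 26-connected zones; NGTDM uses the 26-neighbourhood
# restricted to in-ROI voxels. Texture is computed on the voxel lattice,
# ignoring spacing anisotropy.

# ---- GLCM -------------------------------------------------------------------

# 23 features from one normalised symmetric co-occurrence matrix P (Ng x Ng)
glcmFromMatrix <- function(P) {
  Ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu_x <- sum(seq_len(Ng) * px)
  var_x <- sum((seq_len(Ng) - mu_x)^2 * px)
  mu <- sum(i * P)
  eps_log <- function(v) ifelse(v > 0, log2(v), 0)

  # diagonal (difference) and cross-diagonal (sum) distributions
  pd <- vapply(0:(Ng - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  ps <- vapply(2:(2 * Ng), function(k) sum(P[(i + j) == k]), numeric(1))
  kd <- 0:(Ng - 1)
  ks <- 2:(2 * Ng)
  d_avg <- sum(kd * pd)
  s_avg <- sum(ks * ps)

  HXY <- -sum(P * eps_log(P))
  pxi <- px[i]; pyj <- px[j]   # symmetric: py == px
  HXY1 <- -sum(P * eps_log(pxi * pyj))
  HXY2 <- -sum(pxi * pyj * eps_log(pxi * pyj))
  HX <- -sum(px * eps_log(px))

  ic1 <- if (HX > 0) (HXY - HXY1) / HX else NaN
  ic2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))

  corr <- if (var_x > 0) (sum(i * j * P) - mu_x^2) / var_x else NaN

  c(`Joint-var` = sum((i - mu)^2 * P),
    `Joint-avg` = mu,
    `Joint-entropy` = HXY,
    `Difference-var` = sum((kd - d_avg)^2 * pd),
    `Difference-entropy` = -sum(pd * eps_log(pd)),
    `Difference-avg` = d_avg,
    `Sum-var` = sum((ks - s_avg)^2 * ps),
    `Sum-entropy` = -sum(ps * eps_log(ps)),
    `Sum-avg` = s_avg,
    `Angular-second-moment` = sum(P^2),
    `Contrast` = sum((i - j)^2 * P),
    `Dissimilarity` = sum(abs(i - j) * P),
    `Inv-diff` = sum(P / (1 + abs(i - j))),
    `Inv-diff-mom` = sum(P / (1 + (i - j)^2)),
    `Inv-diff-mom-norm` = sum(P / (1 + (i - j)^2 / Ng^2)),
    `Inverse-variance` = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    `Correlation` = corr,
    `Autocorrelation` = sum(i * j * P),
    `Cluster-tendency` = sum((i + j - 2 * mu_x)^2 * P),
    `Cluster-shade` = sum((i + j - 2 * mu_x)^3 * P),
    `Cluster-prominence` = sum((i + j - 2 * mu_x)^4 * P),
    `First-measure-of-information-correlation` = ic1,
    `Second-measure-of-information-correlation` = ic2)
}

# symmetric co-occurrence counts for one direction; NULL when no pairs
glcmCounts <- function(lev, Ng, off) {
  nb <- shiftArray(lev, -off)  # nb[i] = lev[i + off]
  ok <- !is.na(lev) & !is.na(nb)
  if (!any(ok)) return(NULL)
  a <- lev[ok]; b <- nb[ok]
  cnt <- matrix(tabulate((a - 1L) * Ng + b, nbins = Ng * Ng), Ng, Ng, byrow = TRUE)
  cnt + t(cnt)
}

#' Grey-level co-occurrence features, averaged over the 13 3D directions
#'
#' @param q a `QuantizedROI` from [quantizeROI()].
#' @return Named numeric vector of the 23 GLCM features (`avgCooc_3D_`
#'   prefix). All-`NaN` when no direction has a valid voxel pair.
#' @export
glcm3dFeatures <- function(q) {
  dirs <- latticeDirections(26)
  per_dir <- list()
  for (r in seq_len(nrow(dirs))) {
    cnt <- glcmCounts(q$levels, q$Ng, dirs[r, ])
    if (is.null(cnt)) next
    per_dir[[length(per_dir) + 1L]] <- glcmFromMatrix(cnt / sum(cnt))
  }
  if (!length(per_dir)) {
    warning("GLCM: no valid voxel pairs in any direction; emitting NaN")
    vals <- rep(NaN, length(GLCM_NAMES))
  } else {
    vals <- colMeans(do.call(rbind, per_dir))
  }
  names(vals) <- GLCM_NAMES
  vals
}

# ---- GLRLM ------------------------------------------------------------------

# 16 features from a run-length count matrix R (Ng x max_len) and the
# number of ROI voxels Nv
rlmFromMatrix <- function(R, Nv) {
  Nr <- sum(R)
  i <- row(R); j <- col(R)
  p <- R / Nr
  ri <- rowSums(R); rj <- colSums(R)
  lev <- seq_len(nrow(R)); len <- seq_len(ncol(R))
  mu_i <- sum(lev * ri) / Nr
  mu_j <- sum(len * rj) / Nr
  pn <- p[p > 0]
  c(`SRE` = sum(rj / len^2) / Nr,
    `LRE` = sum(rj * len^2) / Nr,
    `LGRE` = sum(ri / lev^2) / Nr,
    `HGRE` = sum(ri * lev^2) / Nr,
    `SRLGE` = sum(R / (i^2 * j^2)) / Nr,
    `SRHGE` = sum(R * i^2 / j^2) / Nr,
    `LRLGE` = sum(R * j^2 / i^2) / Nr,
    `LRHGE` = sum(R * i^2 * j^2) / Nr,
    `GLN` = sum(ri^2) / Nr,
    `GLNN` = sum(ri^2) / Nr^2,
    `RLN` = sum(rj^2) / Nr,
    `RLNN` = sum(rj^2) / Nr^2,
    `RP` = Nr / Nv,
    `GLV` = sum((i - mu_i)^2 * p),
    `RLV` = sum((j - mu_j)^2 * p),
    `RE` = -sum(pn * log2(pn)))
}

# run-length counts (level x length) along one lattice direction
rlmCounts <- function(lev, Ng, off) {
  d <- dim(lev)
  idx <- which(!is.na(lev))
  if (!length(idx)) return(NULL)
  coords <- arrayInd(idx, d)
  ax0 <- which(off != 0)[1L]
  t_par <- coords[, ax0] * off[ax0]
  key <- coords - outer(t_par, off)  # constant along a line
  key_id <- paste(key[, 1], key[, 2], key[, 3], sep = ",")
  max_len <- max(d)
  cnt <- matrix(0, Ng, max_len)
  ord <- order(key_id, t_par)
  lv <- lev[idx][ord]
  ki <- key_id[ord]
  tt <- t_par[ord]
  n <- length(lv)
  # a new segment starts at a new line or across an out-of-ROI gap
  brk <- c(TRUE, ki[-1] != ki[-n] | diff(tt) != 1L)
  line_id <- cumsum(brk)
  for (ln in split(lv, line_id)) {
    r <- rle(ln)
    for (s in seq_along(r$lengths))
      cnt[r$values[s], r$lengths[s]] <- cnt[r$values[s], r$lengths[s]] + 1
  }
  cnt
}

#' Grey-level run-length features, averaged over the 13 3D directions
#'
#' Runs are maximal streaks of equal grey level along a lattice direction,
#' restricted to in-ROI voxels (out-of-ROI voxels break runs).
#'
#' @param q a `QuantizedROI`.
#' @return Named numeric vector of the 16 GLRLM features (`avg_3D_` prefix).
#' @export
glrlm3dFeatures <- function(q) {
  dirs <- latticeDirections(26)
  Nv <- sum(q$mask)
  per_dir <- lapply(seq_len(nrow(dirs)), function(r) {
    cnt <- rlmCounts(q$levels, q$Ng, dirs[r, ])
    rlmFromMatrix(cnt, Nv)
  })
  vals <- colMeans(do.call(rbind, per_dir))
  names(vals) <- GLRLM_NAMES
  vals
}

# ---- GLSZM ------------------------------------------------------------------

#' Grey-level size-zone features
#'
#' Zones are 26-connected components of equal grey level inside the ROI;
#' a single matrix is used (no direction averaging).
#'
#' @param q a `QuantizedROI`.
#' @return Named numeric vector of the 16 GLSZM features.
#' @export
glszmFeatures <- function(q) {
  lev <- q$levels
  Nv <- sum(q$mask)
  zones_lev <- integer(0); zones_size <- integer(0)
  for (g in sort(unique(lev[q$mask]))) {
    cc <- connectedComponents(!is.na(lev) & lev == g, 26)
    if (any(cc > 0L)) {
      sz <- tabulate(cc[cc > 0L])
      zones_lev <- c(zones_lev, rep(g, length(sz)))
      zones_size <- c(zones_size, sz)
    }
  }
  S <- matrix(0, q$Ng, max(zones_size))
  for (z in seq_along(zones_lev))
    S[zones_lev[z], zones_size[z]] <- S[zones_lev[z], zones_size[z]] + 1
  f <- rlmFromMatrix(S, Nv)
  names(f) <- GLSZM_NAMES  # same algebra, zone-based naming
  f
}

# ---- NGTDM ------------------------------------------------------------------

#' Neighbourhood grey-tone difference features
#'
#' For every ROI voxel with at least one in-ROI 26-neighbour, the absolute
#' difference between its level and the mean level of those neighbours is
#' accumulated per grey level. Coarseness is guarded with epsilon = 1e-12
#' (a constant ROI yields coarseness 1e12); busyness and strength are 0 for
#' a constant ROI.
#'
#' @param q a `QuantizedROI`.
#' @return Named numeric vector of the 5 NGTDM features.
#' @export
ngtdmFeatures <- function(q) {
  lev <- q$levels
  Ng <- q$Ng
  d <- dim(lev)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nb_sum <- array(0, d); nb_n <- array(0, d)
  for (r in seq_len(nrow(offs))) {
    sh <- shiftArray(lev, offs[r, ])
    ok <- !is.na(sh)
    nb_sum[ok] <- nb_sum[ok] + sh[ok]
    nb_n[ok] <- nb_n[ok] + 1
  }
  valid <- q$mask & nb_n > 0
  Nvc <- sum(valid)
  lv <- lev[valid]
  abar <- nb_sum[valid] / nb_n[valid]
  s <- vapply(seq_len(Ng), function(g) sum(abs(g - abar[lv == g])), numeric(1))
  ni <- tabulate(lv, nbins = Ng)
  p <- ni / Nvc
  present <- which(p > 0)
  Ngp <- length(present)
  eps <- 1e-12

  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > eps) 1 / coarse_den else 1 / eps

  contrast <- if (Ngp > 1) {
    pij <- outer(p[present], p[present])
    dij <- outer(present, present, "-")
    (sum(pij * dij^2) / (Ngp * (Ngp - 1))) * (sum(s) / Nvc)
  } else 0

  busy_den <- sum(abs(outer(present * p[present], present * p[present], "-")))
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0

  cmplx <- 0; strength_num <- 0
  if (Ngp > 1) {
    for (a in present) for (b in present) {
      if (a == b) next
      cmplx <- cmplx + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
      strength_num <- strength_num + (p[a] + p[b]) * (a - b)^2
    }
    cmplx <- cmplx / Nvc
  }
  strength <- strength_num / (eps + sum(s))

  vals <- c(coarseness, contrast, busyness, cmplx, strength)
  names(vals) <- NGTDM_NAMES
  vals
}
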