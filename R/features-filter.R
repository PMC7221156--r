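# Filter-bank texture features (category C3): 3D Laws texture energy and
# two-level undecimated Haar wavelet subband statistics.
#
# Both operate on the intensity volume (raw or z-scored) over the ROI
# bounding box with a margin, using symmetric (edge-inclusive) boundary
# padding; statistics are taken over ROI voxels only.

#' 3D Laws texture-energy features (125 features)
#'
#' For every ordered kernel triple (K1, K2, K3) from {L5, E5, S5, R5, W5}
#' (level, edge, spot, ripple, wave), the volume is filtered with the
#' separable product K1 (x-axis) x K2 (y-axis) x K3 (z-axis) and the
#' feature is the mean absolute filter response over ROI voxels.
#'
#' @param vol a [ScanVolume-class].
#' @param roi a [RegionMask-class].
#' @return Named numeric vector of the 125 LAWS3D features in catalog
#'   order (K1 slowest, K3 fastest).
#' @export
laws3dFeatures <- function(vol, roi) {
  assertSameGrid(roi, vol, "roi mask")
  inroi <- roi@voxels > 0L
  if (!any(inroi)) stop("empty ROI", call. = FALSE)
  a <- vol@voxels
  kn <- names(LAWS_KERNELS)
  vals <- numeric(125)
  nm <- character(125)
  pos <- 1L
  for (k1 in kn) {
    ax <- axisFilter(a, LAWS_KERNELS[[k1]], 1L)
    for (k2 in kn) {
      axy <- axisFilter(ax, LAWS_KERNELS[[k2]], 2L)
      for (k3 in kn) {
        resp <- axisFilter(axy, LAWS_KERNELS[[k3]], 3L)
        vals[pos] <- mean(abs(resp[inroi]))
        nm[pos] <- paste0("3D-LawsF-", k1, "-", k2, "-", k3)
        pos <- pos + 1L
      }
    }
  }
  names(vals) <- nm
  vals
}

# Haar analysis filters, orthonormal scaling
HAAR_LO <- c(1, 1) / sqrt(2)
HAAR_HI <- c(1, -1) / sqrt(2)
# level-2 (a-trous) filters: one zero inserted
HAAR_LO2 <- c(1, 0, 1) / sqrt(2)
HAAR_HI2 <- c(1, 0, -1) / sqrt(2)

# the 15 subbands of a two-level undecimated 3D Haar decomposition:
# C1..C7 level-1 details (LLH, LHL, LHH, HLL, HLH, HHL, HHH; letters are
# the x/y/z filters, H = high-pass), C8..C14 level-2 details in the same
# order (computed from the level-1 approximation), C15 the level-2
# approximation.
waveletSubbands <- function(a) {
  bands <- vector("list", 15L)
  combos <- list(c(0, 0, 1), c(0, 1, 0), c(0, 1, 1), c(1, 0, 0),
                 c(1, 0, 1), c(1, 1, 0), c(1, 1, 1))
  filt3 <- function(x, hp, lo, hi) {
    f1 <- if (hp[1]) hi else lo
    f2 <- if (hp[2]) hi else lo
    f3 <- if (hp[3]) hi else lo
    separableFilter3D(x, f1, f2, f3)
  }
  for (b in 1:7)
    bands[[b]] <- filt3(a, combos[[b]], HAAR_LO, HAAR_HI)
  approx1 <- separableFilter3D(a, HAAR_LO, HAAR_LO, HAAR_LO)
  for (b in 1:7)
    bands[[7L + b]] <- filt3(approx1, combos[[b]], HAAR_LO2, HAAR_HI2)
  bands[[15L]] <- separableFilter3D(approx1, HAAR_LO2, HAAR_LO2, HAAR_LO2)
  bands
}

#' Undecimated Haar wavelet subband features (30 features)
#'
#' Two-level undecimated (a-trous) 3D Haar decomposition of the volume;
#' per subband C1..C15 two statistics over ROI voxels: mean absolute
#' coefficient and coefficient energy (sum of squares).
#'
#' @param vol a [ScanVolume-class].
#' @param roi a [RegionMask-class].
#' @return Named numeric vector of the 30 WAVELET3D features.
#' @export
wavelet3dFeatures <- function(vol, roi) {
  assertSameGrid(roi, vol, "roi mask")
  inroi <- roi@voxels > 0L
  if (!any(inroi)) stop("empty ROI", call. = FALSE)
  bands <- waveletSubbands(vol@voxels)
  vals <- numeric(30)
  nm <- character(30)
  for (b in 1:15) {
    coef <- bands[[b]][inroi]
    vals[2 * b - 1] <- mean(abs(coef))
    vals[2 * b] <- sum(coef^2)
    nm[2 * b - 1] <- paste0("3D-Wave-P1-L2-C", b)
    nm[2 * b] <- paste0("3D-Wave-P1-L2-C", b, "-energy")
  }
  names(vals) <- nm
  vals
}
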