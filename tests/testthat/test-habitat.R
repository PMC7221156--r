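test_that("within-lesion habitat keeps the at-or-below-median component", {
  dims <- c(8, 8, 3)
  a <- array(100, dim = dims)
  les <- array(0L, dim = dims)
  les[2:6, 2, 2] <- 1L           # wait: need >= 8 voxels
  les[2:6, 2:3, 2] <- 1L         # 10 voxels total
  # one connected block holding values 1..10; median 5.5 -> threshold <= 5.5
  a[2:6, 2, 2] <- 1:5
  a[2:6, 3, 2] <- 6:10
  adc <- ScanVolume(a, modality = "ADC")
  hab <- habitatWithinLesion(adc, RegionMask(les))
  expect_setequal(a[voxels(hab) > 0], 1:5)
})

test_that("largest-component rule picks the bigger of two equal-ADC blobs", {
  dims <- c(20, 8, 3)
  a <- array(100, dim = dims)
  les <- array(0L, dim = dims)
  les[2:18, 2:6, 2] <- 1L
  les[18, 6, 2] <- 0L        # 84 lesion voxels, half of them low-ADC
  # two low-ADC components of sizes 30 and 12, equal value, separated;
  # median of 42 x 10 and 42 x 100 is 55, so the threshold keeps the blobs
  a[2:7, 2:6, 2] <- 10       # 30 voxels
  a[13:18, 2:3, 2] <- 10     # 12 voxels
  adc <- ScanVolume(a, modality = "ADC")
  hab <- habitatWithinLesion(adc, RegionMask(les))
  expect_identical(foregroundCount(hab), 30L)
  expect_true(all(which(voxels(hab) > 0) %in%
                    which(les > 0 & a == 10 & slice.index(a, 1) <= 7)))
})

test_that("constant-ADC lesion yields the entire lesion as habitat", {
  dims <- c(6, 6, 3)
  a <- array(50, dim = dims)
  les <- array(0L, dim = dims); les[2:4, 2:4, 2] <- 1L
  hab <- habitatWithinLesion(ScanVolume(a, modality = "ADC"), RegionMask(les))
  expect_identical(voxels(hab), les)
})

test_that("sphere habitat converges on a planted low-ADC blob", {
  dims <- c(24, 24, 24)
  a <- array(1000, dim = dims)
  gland <- array(1L, dim = dims)
  # contiguous 20-voxel blob at half background, inside the sphere
  blob <- array(FALSE, dim = dims)
  blob[11:15, 11:12, 12:13] <- TRUE  # 5*2*2 = 20 voxels
  a[blob] <- 500
  les <- array(0L, dim = dims); les[11:14, 11:14, 11:14] <- 1L
  adc <- ScanVolume(a, modality = "ADC")
  hab <- habitatSphere(adc, RegionMask(les), RegionMask(gland, label = "GLAND"),
                       habitatConfig(sphereDiameterMM = 15, deviationK = 1))
  expect_identical(which(voxels(hab) > 0), which(blob))
})

test_that("sphere membership is decided in world millimetres", {
  dims <- c(40, 40, 20)
  sp <- c(1, 1, 3)
  a <- array(0, dim = dims)
  gland <- RegionMask(array(1L, dim = dims), spacing = sp, label = "GLAND")
  # lesion centred at voxel (20,20,10) (0-based index as world (20,20,27) wait:
  # world x = (i-1)*dx; centroid of the single-voxel lesion at index (21,21,11)
  les <- array(0L, dim = dims); les[21, 21, 11] <- 1L
  # distinct markers: in-plane 7 mm away (inside r=7.5) and 3 voxels axially
  # (9 mm, outside r=7.5)
  a[28, 21, 11] <- -100   # 7 mm in-plane
  a[21, 21, 14] <- -100   # 9 mm axial
  adc <- ScanVolume(a, spacing = sp, modality = "ADC")
  hab <- habitatSphere(adc, RegionMask(les, spacing = sp), gland,
                       habitatConfig(sphereDiameterMM = 15))
  sel <- which(voxels(hab) > 0, arr.ind = TRUE)
  expect_true(nrow(sel) >= 1)
  expect_true(any(sel[, 1] == 28 & sel[, 2] == 21 & sel[, 3] == 11))
  expect_false(any(sel[, 3] == 14))
})

test_that("uniform ADC in the sphere degenerates to the full search region", {
  dims <- c(16, 16, 16)
  a <- array(777, dim = dims)
  gland <- RegionMask(array(1L, dim = dims), label = "GLAND")
  les <- array(0L, dim = dims); les[7:10, 7:10, 7:10] <- 1L
  hab <- habitatSphere(ScanVolume(a, modality = "ADC"), RegionMask(les), gland,
                       habitatConfig(sphereDiameterMM = 10, deviationK = 1))
  # expected: largest component of {ADC <= mu} = whole sphere-gland intersection
  ctr <- colMeans(which(les > 0, arr.ind = TRUE)) - 1
  d2 <- outer(outer((seq_len(16) - 1 - ctr[1])^2, (seq_len(16) - 1 - ctr[2])^2, "+"),
              (seq_len(16) - 1 - ctr[3])^2, "+")
  expect_identical(which(voxels(hab) > 0), which(d2 <= 25))
})

test_that("habitats respect containment, connectivity and determinism", {
  coh <- generatePhantomCohort(phantomConfig(nPatients = 3, seed = 21))
  for (pat in coh$patients) {
    adc <- pat$test$volumes$ADC
    les <- pat$test$lesions[[1]]$mask
    hm <- habitatWithinLesion(adc, les)
    hs <- habitatSphere(adc, les, pat$gland)
    expect_true(all(voxels(hm) <= voxels(les)))
    expect_true(all(voxels(hs) <= voxels(pat$gland)))
    expect_gte(foregroundCount(hm), 1L)
    expect_lte(foregroundCount(hm), foregroundCount(les))
    # connectedness under 26-connectivity
    n_comp <- function(m) max(radrepeat:::connectedComponents(voxels(m) > 0, 26))
    expect_identical(n_comp(hm), 1L)
    expect_identical(n_comp(hs), 1L)
    # determinism
    expect_identical(voxels(habitatWithinLesion(adc, les)), voxels(hm))
    expect_identical(voxels(habitatSphere(adc, les, pat$gland)), voxels(hs))
  }
})

test_that("sphere habitat errors when the search region is empty", {
  dims <- c(30, 30, 10)
  gl <- array(0L, dim = dims); gl[2:5, 2:5, 2:4] <- 1L
  les <- array(0L, dim = dims); les[25:28, 25:28, 6:8] <- 1L
  adc <- ScanVolume(array(1000, dim = dims), modality = "ADC")
  expect_error(habitatSphere(adc, RegionMask(les), RegionMask(gl, label = "GLAND"),
                             habitatConfig(sphereDiameterMM = 5)),
               "outside gland")
})
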