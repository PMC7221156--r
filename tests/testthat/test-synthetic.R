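test_that("phantom cohorts are deterministic given the seed", {
  c1 <- generatePhantomCohort(phantomConfig(nPatients = 2, seed = 71))
  c2 <- generatePhantomCohort(phantomConfig(nPatients = 2, seed = 71))
  expect_identical(voxels(c1$patients[[1]]$test$volumes$ADC),
                   voxels(c2$patients[[1]]$test$volumes$ADC))
  expect_identical(voxels(c1$patients[[2]]$retest$lesions[[1]]$mask),
                   voxels(c2$patients[[2]]$retest$lesions[[1]]$mask))
  c3 <- generatePhantomCohort(phantomConfig(nPatients = 2, seed = 72))
  expect_false(identical(voxels(c1$patients[[1]]$test$volumes$ADC),
                         voxels(c3$patients[[1]]$test$volumes$ADC)))
})

test_that("zero noise and zero jitter reproduce test bitwise at retest", {
  coh <- generatePhantomCohort(phantomConfig(nPatients = 2, retestNoiseSD = 0,
                                             boundaryJitterMM = 0, seed = 73))
  for (pat in coh$patients) {
    expect_identical(voxels(pat$test$volumes$T2W), voxels(pat$retest$volumes$T2W))
    expect_identical(voxels(pat$test$volumes$ADC), voxels(pat$retest$volumes$ADC))
    expect_identical(voxels(pat$test$lesions[[1]]$mask),
                     voxels(pat$retest$lesions[[1]]$mask))
  }
})

test_that("phantom anatomy is consistent: lesions in gland, ADC contrast planted", {
  coh <- generatePhantomCohort(phantomConfig(nPatients = 4, seed = 74))
  for (pat in coh$patients) {
    les <- pat$test$lesions[[1]]
    expect_true(all(voxels(les$mask) <= voxels(pat$gland)))
    adc <- voxels(pat$test$volumes$ADC)
    core <- voxels(les$core) > 0
    gland_only <- voxels(pat$gland) > 0 & voxels(les$mask) == 0
    expect_lt(mean(adc[core]), mean(adc[gland_only]))
  }
})

test_that("within-lesion habitat recovers the planted core", {
  coh <- generatePhantomCohort(phantomConfig(nPatients = 5, seed = 75))
  for (pat in coh$patients) {
    les <- pat$test$lesions[[1]]
    hab <- habitatWithinLesion(pat$test$volumes$ADC, les$mask)
    expect_gte(diceCoef(voxels(hab) > 0, voxels(les$core) > 0), 0.8)
  }
})

test_that("designed matrices hit their population concordance targets", {
  targets <- c(0.3, 0.65, 0.9)
  cfg <- designedFeatureConfig(nSubjects = 500, nFeatures = 150,
                               targetCCC = rep(targets, each = 50), seed = 76)
  rec <- screenFeatures(generateDesignedFeatures(cfg))
  idx <- as.integer(sub("^F(\\d+):.*", "\\1", rec$feature_id))
  for (t in seq_along(targets)) {
    block <- idx > (t - 1) * 50 & idx <= t * 50
    expect_lt(abs(mean(rec$ccc[block]) - targets[t]), 0.03)
  }
})

test_that("target 1 gives exact concordance and duplicate blocks collapse", {
  cfg <- designedFeatureConfig(nSubjects = 40, nFeatures = 6,
                               targetCCC = c(1, 1, 1, 0.8, 0.8, 0.8),
                               duplicateBlocks = list(1:3), seed = 77)
  fm <- generateDesignedFeatures(cfg)
  rec <- screenFeatures(fm)
  expect_true(all(rec$ccc[1:3] == 1))
  avg <- radrepeat:::subjectAverages(fm, "DESIGNED", "SIM", rec$feature_id)
  sel <- reduceFeatures(rec[grepl("^F[123]:", rec$feature_id), ], avg,
                        redundancyConfig(0.99))
  expect_length(sel, 1L)
})

test_that("cohorts round-trip through NIfTI + manifest", {
  coh <- generatePhantomCohort(phantomConfig(nPatients = 2, seed = 78))
  dir <- file.path(tempdir(), "cohort-rt")
  manifest <- writeCohort(coh, dir)
  coh2 <- loadCohort(manifest)
  expect_length(coh2$patients, 2L)
  for (p in 1:2) {
    expect_identical(
      as.vector(voxels(coh2$patients[[p]]$test$volumes$ADC)),
      as.vector(voxels(coh$patients[[p]]$test$volumes$ADC)))
    expect_identical(foregroundCount(coh2$patients[[p]]$gland),
                     foregroundCount(coh$patients[[p]]$gland))
    expect_identical(
      voxels(coh2$patients[[p]]$retest$lesions[[1]]$mask),
      voxels(coh$patients[[p]]$retest$lesions[[1]]$mask))
  }
  unlink(dir, recursive = TRUE)
})
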