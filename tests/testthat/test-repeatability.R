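test_that("concordance correlation matches hand-computed cases", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(ccc(c(1, 2, 3, 4), c(2, 3, 4, 5)), 2 * 1.25 / 3.5)
  expect_error(ccc(c(1, 2), c(1, 2)), "at least 3")
})

test_that("degenerate concordance conventions", {
  expect_equal(ccc(c(2, 2, 2), c(2, 2, 2)), 1)   # constant and equal
  expect_equal(ccc(c(2, 2, 2), c(5, 5, 5)), 0)   # constant and unequal
  expect_equal(ccc(c(2, 2, 2), c(1, 5, 9)), 0)   # one constant
})

test_that("dynamic range follows the defining arithmetic and stays in [0, 1]", {
  expect_equal(dynamicRange(c(0, 10), c(2, 8)), 0.8)
  expect_equal(dynamicRange(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(dynamicRange(c(3, 3), c(3, 3)), 0)  # degenerate pooled range
  set.seed(51)
  for (i in 1:50) {
    x <- rnorm(10); y <- rnorm(10)
    d <- dynamicRange(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("dynamic range decreases as test-retest differences grow", {
  set.seed(52)
  x <- rnorm(30)
  noise <- rnorm(30)
  drs <- vapply(c(0.05, 0.2, 0.5, 1), function(s) dynamicRange(x, x + s * noise),
                numeric(1))
  expect_true(all(diff(drs) < 0))
})

test_that("ccc and dynamicRange agree with the naive formulas", {
  set.seed(53)
  for (i in 1:200) {
    x <- rnorm(20, sd = runif(1, 0.1, 10))
    y <- x * runif(1, 0.5, 2) + rnorm(20)
    expect_equal(ccc(x, y), ccc_naive(x, y), tolerance = 1e-12)
    expect_equal(dynamicRange(x, y), dr_naive(x, y), tolerance = 1e-12)
  }
})

test_that("ccc is affine-invariant and bounded by Pearson correlation", {
  set.seed(54)
  for (i in 1:30) {
    x <- rnorm(15); y <- x + rnorm(15, sd = 0.5)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(ccc(a * x + b, a * y + b), ccc(x, y), tolerance = 1e-10)
    expect_lte(abs(ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
})

test_that("screen computes per-feature records with monotone pass nesting", {
  cfg <- designedFeatureConfig(nSubjects = 60, nFeatures = 30,
                               targetCCC = runif(30), seed = 55)
  fm <- generateDesignedFeatures(cfg)
  rec <- screenFeatures(fm)
  expect_identical(nrow(rec), 30L)
  expect_true(all(rec$n_pairs == 60))
  pass_cols <- grep("^pass_", names(rec), value = TRUE)
  counts <- colSums(rec[pass_cols])
  expect_true(all(diff(counts) <= 0))  # non-increasing with rising cutoff
  # pass(c) implies pass(c') for c' < c, row-wise
  for (k in seq_along(pass_cols)[-1])
    expect_true(all(rec[[pass_cols[k]]] <= rec[[pass_cols[k - 1]]]))
})

test_that("identical test and retest pass every cutoff", {
  fm <- generateDesignedFeatures(designedFeatureConfig(
    nSubjects = 20, nFeatures = 5, targetCCC = 1, seed = 56))
  rec <- screenFeatures(fm)
  expect_true(all(rec$ccc == 1))
  expect_true(all(rec$dr == 1))
  expect_true(all(unlist(rec[grep("^pass_", names(rec))])))
})

test_that("features with too few complete pairs are flagged, not counted", {
  d <- expand.grid(patient_id = c("P1", "P2", "P3"), lesion_id = "L1",
                   timepoint = c("TEST", "RETEST"),
                   region_variant = "DESIGNED", modality = "SIM",
                   feature_id = c("F1:a", "F2:b"), stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d))
  d$value[d$feature_id == "F2:b" & d$patient_id != "P1"] <- NaN
  expect_warning(rec <- screenFeatures(FeatureMatrix(d)), "complete pairs")
  expect_true(is.nan(rec$ccc[rec$feature_id == "F2:b"]))
  expect_false(any(unlist(rec[rec$feature_id == "F2:b",
                              grep("^pass_", names(rec))])))
})
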