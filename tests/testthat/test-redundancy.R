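test_that("coefficient of determination matches hand cases and naive formula", {
  expect_equal(rsq(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(rsq(c(1, 2, 3), c(1, 3, 2)), 0.25)
  expect_equal(rsq(c(1, 1, 1), c(1, 2, 3)), 0)  # constant -> no dependence
  set.seed(61)
  for (i in 1:100) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(rsq(x, y), rsq_naive(x, y), tolerance = 1e-12)
    expect_equal(rsq(x, y), rsq(y, x))
  }
})

test_that("greedy reduction follows the worked three-feature example", {
  # R^2(A,B) >= cutoff, everything else below; DR: A=0.7, B=0.9, C=0.8
  set.seed(62)
  base <- rnorm(30)
  avg <- cbind(A = base + rnorm(30, sd = 0.01),  # R^2(A,B) ~ 1
               B = base,
               C = rnorm(30))
  rec <- data.frame(feature_id = c("A", "B", "C"), dr = c(0.7, 0.9, 0.8))
  stopifnot(rsq(avg[, "A"], avg[, "B"]) >= 0.99,
            rsq(avg[, "A"], avg[, "C"]) < 0.99,
            rsq(avg[, "B"], avg[, "C"]) < 0.99)
  sel <- reduceFeatures(rec, avg, redundancyConfig(0.99))
  expect_identical(sel, c("B", "C"))
})

test_that("exact duplicates collapse to the single highest-DR copy", {
  set.seed(63)
  x <- rnorm(25)
  avg <- cbind(`F1:a` = x, `F2:b` = 2 * x + 1, `F3:c` = rnorm(25))
  rec <- data.frame(feature_id = c("F1:a", "F2:b", "F3:c"),
                    dr = c(0.75, 0.9, 0.5))
  sel <- reduceFeatures(rec, avg, redundancyConfig(0.99))
  expect_identical(sel, c("F2:b", "F3:c"))
  # equal-DR copies: the lower catalog index survives
  rec$dr <- c(0.9, 0.9, 0.5)
  expect_identical(reduceFeatures(rec, avg, redundancyConfig(0.99)),
                   c("F1:a", "F3:c"))
})

test_that("cutoff 1.0 with no exact duplicates retains everything", {
  set.seed(64)
  avg <- matrix(rnorm(20 * 6), 20, 6,
                dimnames = list(NULL, sprintf("F%d:x", 1:6)))
  rec <- data.frame(feature_id = colnames(avg), dr = runif(6))
  sel <- reduceFeatures(rec, avg, redundancyConfig(1.0))
  expect_setequal(sel, colnames(avg))
})

test_that("every removed feature is redundant with some representative", {
  set.seed(65)
  for (rep in 1:10) {
    n_feat <- 40
    base <- matrix(rnorm(30 * 8), 30, 8)
    avg <- base[, sample(8, n_feat, replace = TRUE)] +
      matrix(rnorm(30 * n_feat, sd = 0.2), 30, n_feat)
    colnames(avg) <- sprintf("F%d:x", seq_len(n_feat))
    rec <- data.frame(feature_id = colnames(avg), dr = runif(n_feat))
    cutoff <- 0.8
    sel <- reduceFeatures(rec, avg, redundancyConfig(cutoff))
    removed <- setdiff(colnames(avg), sel)
    for (f in removed) {
      r2 <- vapply(sel, function(s) rsq(avg[, f], avg[, s]), numeric(1))
      expect_gte(max(r2), cutoff)
    }
  }
})

test_that("lowering the R^2 cutoff never increases the survivor count", {
  set.seed(66)
  base <- matrix(rnorm(25 * 5), 25, 5)
  avg <- base[, sample(5, 30, replace = TRUE)] +
    matrix(rnorm(25 * 30, sd = 0.3), 25, 30)
  colnames(avg) <- sprintf("F%d:x", 1:30)
  rec <- data.frame(feature_id = colnames(avg), dr = runif(30))
  sizes <- vapply(c(0.999, 0.99, 0.95, 0.9, 0.8, 0.6),
                  function(co) length(reduceFeatures(rec, avg, redundancyConfig(co))),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("selection is deterministic", {
  set.seed(67)
  avg <- matrix(rnorm(20 * 10), 20, 10,
                dimnames = list(NULL, sprintf("F%d:x", 1:10)))
  rec <- data.frame(feature_id = colnames(avg), dr = runif(10))
  expect_identical(reduceFeatures(rec, avg, redundancyConfig(0.9)),
                   reduceFeatures(rec, avg, redundancyConfig(0.9)))
})
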