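test_that("t-test selection behaves at the null, under signal, and at alpha = 0", {
  set.seed(61)
  # strong signal: one feature shifted by 5 pooled SDs is always caught
  for (rep in 1:20) {
    n <- 40
    x <- matrix(rnorm(n * 10), n, 10)
    y <- rep(c(0L, 1L), each = n / 2)
    x[y == 1L, 4] <- x[y == 1L, 4] + 5
    mask <- ttestSelect(x, y)
    expect_true(mask[4])
  }
  # alpha = 0 selects nothing even with signal
  expect_equal(sum(ttestSelect(x, y, alpha = 0)), 0L)
  # null: selected fraction is near alpha (loose 3x bound at P = 50)
  set.seed(62)
  picked <- vapply(1:40, function(i) {
    x <- matrix(rnorm(60 * 50), 60, 50)
    sum(ttestSelect(x, rep(c(0L, 1L), each = 30)))
  }, numeric(1))
  expect_lt(mean(picked), 3 * 0.05 * 50)
  expect_gt(mean(picked), 0)
})

test_that("t-test selection rejects invalid inputs and flat features", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(ttestSelect(x, rep(1L, 10)), "both classes")
  expect_error(ttestSelect(x[1:3, ], c(0L, 1L, 0L)), "at least 4")
  x[, 2] <- 7
  expect_warning(mask <- ttestSelect(x, rep(c(0L, 1L), 5)),
                 "zero variance")
  expect_false(mask[2])
})

test_that("confusion metrics match hand arithmetic and boundary cases", {
  m <- evaluateConfusion(35, 10, 40, 6)
  expect_equal(m[["sen"]], 35 / 45)
  expect_equal(m[["spe"]], 40 / 46)
  expect_equal(m[["acc"]], 75 / 91)
  expect_equal(unname(evaluateConfusion(7, 0, 9, 0)[c("acc", "sen", "spe")]),
               c(1, 1, 1))
  expect_equal(unname(evaluateConfusion(0, 7, 0, 9)[c("acc", "sen", "spe")]),
               c(0, 0, 0))
  expect_error(evaluateConfusion(0, 0, 3, 1), "undefined metric")
  expect_error(evaluateConfusion(-1, 2, 3, 1), "nonnegative")
})

test_that("ACC is the class-weighted mean of SEN and SPE on every pool", {
  set.seed(63)
  x <- rbind(matrix(rnorm(200), 20), matrix(rnorm(200, 1), 20))
  y <- rep(c(0L, 1L), each = 20)
  res <- repeatedCV(x, y, folds = 5, reps = 4, seed = 63)
  nPos <- sum(y == 1L)
  nNeg <- sum(y == 0L)
  with(res@perRepetition,
    expect_equal(acc * (nPos + nNeg), sen * nPos + spe * nNeg,
                 tolerance = 1e-12))
})

test_that("perfect separation yields perfect metrics in every repetition", {
  set.seed(64)
  n <- 40
  x <- matrix(rnorm(n * 8), n, 8)
  y <- rep(c(0L, 1L), each = n / 2)
  x[y == 1L, 3] <- x[y == 1L, 3] + 10
  res <- repeatedCV(x, y, folds = 10, reps = 3, seed = 64)
  expect_equal(res@perRepetition$acc, rep(1, 3))
  expect_equal(res@perRepetition$sen, rep(1, 3))
  expect_equal(res@perRepetition$spe, rep(1, 3))
  expect_equal(res@perRepetition$auc, rep(1, 3))
})

test_that("permuted labels classify at chance level", {
  set.seed(65)
  accs <- vapply(1:20, function(i) {
    x <- matrix(rnorm(60 * 10), 60, 10)
    y <- sample(rep(c(0L, 1L), each = 30))
    repeatedCV(x, y, folds = 5, reps = 2, seed = 1000 + i)@accMean
  }, numeric(1))
  expect_gt(mean(accs), 0.5 - 0.12)
  expect_lt(mean(accs), 0.5 + 0.12)
})

test_that("results are a pure function of the seed", {
  set.seed(66)
  x <- rbind(matrix(rnorm(100), 10), matrix(rnorm(100, 0.5), 10))
  y <- rep(c(0L, 1L), each = 10)
  a <- repeatedCV(x, y, folds = 10, reps = 1, seed = 99)
  b <- repeatedCV(x, y, folds = 10, reps = 1, seed = 99)
  expect_identical(a@perRepetition, b@perRepetition)
  expect_identical(a@selectedCounts, b@selectedCounts)
  c <- repeatedCV(x, y, folds = 10, reps = 1, seed = 100)
  expect_false(identical(a@perRepetition, c@perRepetition))
})

test_that("nested selection avoids the optimism of full-data selection", {
  # on pure noise with many features, selecting on the full data set
  # (including the future test folds) leaks label information into the
  # classifier; training-fold-only selection must not show that inflation
  set.seed(67)
  gap <- vapply(1:8, function(i) {
    x <- matrix(rnorm(40 * 200), 40, 200)
    y <- rep(c(0L, 1L), each = 20)
    s <- 2000 + i
    unnested <- repeatedCV(x, y, folds = 5, reps = 2, seed = s,
                           nested = FALSE)@accMean
    nested <- repeatedCV(x, y, folds = 5, reps = 2, seed = s)@accMean
    c(nested, unnested)
  }, numeric(2))
  expect_lt(mean(gap[1, ]), 0.5 + 0.12)      # nested stays at chance
  expect_gt(mean(gap[2, ]) - mean(gap[1, ]), 0.05)  # leakage inflates
})

test_that("class sizes below the fold count are rejected", {
  x <- matrix(rnorm(60), 12, 5)
  y <- c(rep(0L, 9), rep(1L, 3))
  expect_error(repeatedCV(x, y, folds = 5, reps = 1, seed = 1),
               "invalid cross-validation")
  expect_error(repeatedCV(x, y, folds = 3, reps = 1),
               "seed")
})
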