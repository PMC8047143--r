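test_that("group covariances are block-constant with the designed attenuation", {
  spec <- CohortSpec(nPos = 2, nNeg = 2, P = 10,
                     modules = list(1:5, 6:10), affectedModules = 1L,
                     rhoWithin = 0.6, rhoBetween = 0.1, effectDelta = 0.3)
  pos <- buildGroupCovariance(spec, positive = TRUE)
  neg <- buildGroupCovariance(spec, positive = FALSE)
  expect_equal(neg[1, 2], 0.6)
  expect_equal(neg[6, 7], 0.6)
  expect_equal(neg[1, 6], 0.1)
  expect_equal(unname(diag(neg)), rep(1, 10))
  expect_equal(pos[1, 2], 0.3)        # attenuated module
  expect_equal(pos[6, 7], 0.6)        # untouched module
  # no attenuation: both groups coincide
  spec0 <- CohortSpec(nPos = 2, nNeg = 2, P = 10,
                      modules = list(1:5, 6:10), effectDelta = 0)
  expect_equal(buildGroupCovariance(spec0, TRUE),
               buildGroupCovariance(spec0, FALSE))
})

test_that("a two-region module carries exactly its target correlation", {
  spec <- CohortSpec(nPos = 1, nNeg = 1, P = 4, modules = list(1:2),
                     affectedModules = integer(0), rhoWithin = 0.6,
                     rhoBetween = 0, effectDelta = 0)
  S <- buildGroupCovariance(spec, FALSE)
  expect_equal(S[1, 2], 0.6)
  expect_equal(S[3, 4], 0)
})

test_that("implied covariances are PSD after at most minimal shrinkage", {
  set.seed(81)
  for (rep in 1:10) {
    P <- sample(c(12L, 20L, 30L), 1)
    sz <- sample(c(3L, 5L), 1)
    spec <- CohortSpec(nPos = 2, nNeg = 2, P = P,
                       modules = split(seq_len(P),
                                       rep(seq_len(P %/% sz), each = sz,
                                           length.out = P)),
                       rhoWithin = runif(1, 0.3, 0.8),
                       rhoBetween = runif(1, 0, 0.2),
                       effectDelta = 0.2, affectedModules = 1L)
    for (g in c(TRUE, FALSE)) {
      S <- buildGroupCovariance(spec, g)
      expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
                 0)
      expect_gte(attr(S, "shrinkage"), 0)
    }
  }
})

test_that("long series recover the target within-module correlation", {
  spec <- CohortSpec(nPos = 1, nNeg = 0, P = 6, Q = 10000,
                     modules = list(1:3, 4:6), affectedModules = integer(0),
                     rhoWithin = 0.6, rhoBetween = 0.1, effectDelta = 0,
                     arCoeff = 0.3, noiseSd = 0, seed = 82)
  ts <- sampleCohort(spec)$subjects[[1]]
  S <- cor(tsMatrix(ts))
  expect_lt(abs(S[1, 2] - 0.6), 0.05)
  expect_lt(abs(S[1, 4] - 0.1), 0.05)
})

test_that("the same seed reproduces the cohort bit for bit", {
  spec <- CohortSpec(nPos = 3, nNeg = 3, P = 8, Q = 50,
                     modules = list(1:4, 5:8), seed = 83)
  a <- sampleCohort(spec)
  b <- sampleCohort(spec)
  expect_identical(lapply(a$subjects, tsMatrix),
                   lapply(b$subjects, tsMatrix))
  expect_identical(a$manifest, b$manifest)
  spec2 <- CohortSpec(nPos = 3, nNeg = 3, P = 8, Q = 50,
                      modules = list(1:4, 5:8), seed = 84)
  expect_false(identical(tsMatrix(sampleCohort(spec2)$subjects[[1]]),
                         tsMatrix(a$subjects[[1]])))
})

test_that("sample covariance converges to the design as Q grows", {
  err <- vapply(c(100L, 1000L, 10000L), function(Q) {
    spec <- CohortSpec(nPos = 1, nNeg = 0, P = 6, Q = Q,
                       modules = list(1:3, 4:6),
                       affectedModules = integer(0), effectDelta = 0,
                       arCoeff = 0, noiseSd = 0, seed = 85)
    S <- cov(tsMatrix(sampleCohort(spec)$subjects[[1]]))
    target <- buildGroupCovariance(spec, FALSE)
    max(abs(S - target))
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.06)
})

test_that("manifest records labels, per-subject seeds and shrinkage", {
  spec <- CohortSpec(nPos = 2, nNeg = 3, P = 6, Q = 30,
                     modules = list(1:3, 4:6), seed = 86)
  m <- sampleCohort(spec)$manifest
  expect_equal(nrow(m), 5L)
  expect_equal(sum(m$label == 1L), 2L)
  expect_equal(anyDuplicated(m$seed), 0L)
  expect_true(all(m$shrinkage >= 0))
})

test_that("infeasible correlation structures are refused", {
  # strongly negative between-module vs within would need huge shrinkage;
  # force infeasibility through a validity-breaking spec instead
  expect_error(CohortSpec(rhoWithin = 0.2, rhoBetween = 0.4),
               "rhoBetween")
  expect_error(CohortSpec(effectDelta = 0.9, rhoWithin = 0.6),
               "effectDelta")
})
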