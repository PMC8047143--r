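test_that("soft threshold matches hand arithmetic and a scalar loop", {
  expect_equal(softThreshold(matrix(0.8), 0.25), matrix(0.55))
  expect_equal(softThreshold(matrix(-0.1), 0.25), matrix(0))
  M <- matrix(rnorm(20), 4, 5)
  expect_equal(softThreshold(M, 0), M)
  set.seed(31)
  for (rep in 1:5) {
    M <- matrix(rnorm(36, sd = 2), 6, 6)
    t <- runif(1, 0, 1.5)
    expected <- M
    for (i in seq_along(M))
      expected[i] <- sign(M[i]) * max(abs(M[i]) - t, 0)
    expect_equal(softThreshold(M, t), expected)
  }
  expect_error(softThreshold(M, -0.1), "invalid threshold")
})

test_that("SHMR objective agrees with term-by-term evaluation", {
  set.seed(32)
  S0 <- randomCorrelationLike(6)
  Lh <- laplacianMatrix(buildHypergraph(S0, 2))
  W <- randomSymmetric(6)
  expect_equal(shmrObjective(S0, S0, Lh, 0, 0), 0)
  expect_equal(shmrObjective(matrix(0, 6, 6), S0, Lh, 0, 0), sum(S0^2))
  lam <- 0.3; beta <- 0.7
  fit <- sum((W - S0)^2)
  l1 <- lam * sum(abs(W))
  manifold <- beta * sum(diag(t(W) %*% Lh %*% W))
  expect_equal(shmrObjective(W, S0, Lh, lam, beta), fit + l1 + manifold)
})

test_that("solveShmr reduces to the Pearson matrix when unregularized", {
  set.seed(33)
  S0 <- randomCorrelationLike(8)
  Lh <- laplacianMatrix(buildHypergraph(S0, 3))
  res <- solveShmr(S0, Lh, SolverConfig(0, 0))
  expect_equal(res@WStar, S0, tolerance = 1e-12)
  expect_true(res@converged)
})

test_that("beta = 0 solves reach the closed-form soft-threshold optimum", {
  set.seed(34)
  for (rep in 1:10) {
    S0 <- randomSymmetric(10)
    lam <- runif(1, 0.01, 0.8)
    res <- solveShmr(S0, diag(10) * 0, SolverConfig(lam, 0))
    expect_lt(max(abs(res@WStar - sign(S0) * pmax(abs(S0) - lam / 2, 0))),
              1e-6)
  }
})

test_that("literal threshold scaling reproduces the printed rule", {
  set.seed(35)
  S0 <- randomSymmetric(6)
  lam <- 0.4
  res <- solveShmr(S0, diag(6) * 0,
                   SolverConfig(lam, 0, thresholdScaling = "literal"))
  expect_equal(res@WStar, sign(S0) * pmax(abs(S0) - lam, 0),
               tolerance = 1e-8)
})

test_that("objective trace is non-increasing under the Lipschitz step", {
  set.seed(36)
  for (rep in 1:10) {
    P <- sample(5:12, 1)
    S0 <- randomCorrelationLike(P)
    Lh <- laplacianMatrix(buildHypergraph(S0, min(3, P - 1)))
    res <- solveShmr(S0, Lh, SolverConfig(runif(1, 0, 0.5),
                                          runif(1, 0, 0.5)))
    expect_true(all(diff(res@objectiveTrace) <= 1e-10))
  }
})

test_that("a wildly large fixed step raises a divergence error", {
  set.seed(37)
  S0 <- randomCorrelationLike(6)
  expect_error(
    solveShmr(S0, diag(6) * 0,
              SolverConfig(0.1, 0, stepRule = "fixed", fixedStep = 100)),
    "divergence")
})

test_that("solutions are perturbation-optimal for the solved objective", {
  set.seed(38)
  S0 <- randomCorrelationLike(4)
  Lh <- laplacianMatrix(buildHypergraph(S0, 2))
  lam <- 0.1; beta <- 0.1
  res <- solveShmr(S0, Lh, SolverConfig(lam, beta, maxIter = 5000L,
                                        tol = 1e-14))
  # the iteration minimizes the composite with manifold weight beta / 2
  obj <- function(W) shmrObjective(W, S0, Lh, lam, beta / 2)
  o0 <- obj(res@WStar)
  worse <- vapply(seq_len(1000), function(i)
    obj(res@WStar + 1e-3 * randomSymmetric(4)), numeric(1))
  expect_true(all(worse >= o0 - 1e-12))
})

test_that("off-diagonal support shrinks as lambda grows", {
  set.seed(39)
  S0 <- randomCorrelationLike(12)
  Lh <- laplacianMatrix(buildHypergraph(S0, 5))
  nnz <- vapply(c(0, 2^-4, 2^-3, 2^-2, 2^-1), function(lam) {
    W <- solveShmr(S0, Lh, SolverConfig(lam, 2^-3))@WStar
    sum(W[upper.tri(W)] != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("re-solving from the symmetrized output barely moves the objective", {
  set.seed(40)
  S0 <- randomCorrelationLike(8)
  Lh <- laplacianMatrix(buildHypergraph(S0, 3))
  cfg <- SolverConfig(0.1, 0.2)
  res <- solveShmr(S0, Lh, cfg)
  expect_equal(res@WStar, t(res@WStar))
  res2 <- solveShmr(res@WStar, Lh, SolverConfig(0, 0))
  expect_equal(res2@WStar, res@WStar, tolerance = 1e-10)
})

test_that("simple-graph Laplacian takes its closed forms and matches arithmetic", {
  expect_equal(simpleGraphLaplacian(diag(4)), matrix(0, 4, 4))
  P <- 5
  expect_equal(simpleGraphLaplacian(matrix(1, P, P)),
               diag(P) - matrix(1 / P, P, P))
  set.seed(41)
  S <- randomCorrelationLike(7)
  A <- abs(S)
  D <- diag(rowSums(A))
  expected <- diag(7) - solve(sqrt(D)) %*% A %*% solve(sqrt(D))
  expect_equal(simpleGraphLaplacian(S), expected, tolerance = 1e-12)
  expect_error(simpleGraphLaplacian(matrix(0, 3, 3)), "degenerate graph")
})

test_that("regression family with orthonormal X collapses to zero", {
  set.seed(42)
  X <- qr.Q(qr(matrix(rnorm(150), 30, 5)))
  res <- solveRegressionFamily(X, NULL,
    SolverConfig(0, 0, objectiveFamily = "regression_fit"))
  expect_equal(res@WStar, matrix(0, 5, 5), tolerance = 1e-8)
})

test_that("duplicated regions attract the strongest regression weight", {
  set.seed(43)
  x <- rnorm(40)
  X <- cbind(x, x, matrix(rnorm(40 * 3), 40, 3))
  X <- scale(X, scale = apply(X, 2, function(c) sqrt(sum(c^2))))
  res <- solveRegressionFamily(X, NULL,
    SolverConfig(0.05, 0, objectiveFamily = "regression_fit"))
  W <- abs(res@WStar)
  expect_gt(W[1, 2], max(W[1, 3:5], W[2, 3:5]))
})

test_that("sparse regression objective matches an independent lasso solver", {
  skip_if_not_installed("glmnet")
  set.seed(44)
  X <- matrix(rnorm(150), 30, 5)
  lam <- 0.1
  res <- solveRegressionFamily(X, NULL,
    SolverConfig(lam, 0, maxIter = 20000L, tol = 1e-12,
                 objectiveFamily = "regression_fit"))
  # the zero-diagonal joint problem decouples into one lasso per column;
  # glmnet minimizes (1/2n)||y - Xb||^2 + s||b||_1, so s = lam / (2n)
  objective <- function(W) sum((X - X %*% W)^2) + lam * sum(abs(W))
  n <- nrow(X)
  Wref <- matrix(0, 5, 5)
  for (j in 1:5) {
    fit <- glmnet::glmnet(X[, -j], X[, j], lambda = lam / (2 * n),
                          intercept = FALSE, standardize = FALSE,
                          thresh = 1e-14)
    Wref[-j, j] <- as.numeric(fit$beta)
  }
  # compare before symmetrization via objective values (both near-optimal)
  expect_lt(abs(objective(Wref) -
                utils::tail(res@objectiveTrace, 1)), 1e-4)
})

test_that("regression traces descend and the diagonal stays clamped", {
  set.seed(45)
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 6), 40, 6)
    Xs <- standardizeWindow(X)
    L <- simpleGraphLaplacian(crossprod(Xs))
    res <- solveRegressionFamily(Xs, L,
      SolverConfig(0.05, 0.2, objectiveFamily = "regression_fit"))
    expect_true(all(diff(res@objectiveTrace) <= 1e-10))
    expect_equal(unname(diag(res@WStar)), rep(0, 6))
  }
})

test_that("family/config mismatches are rejected", {
  S0 <- diag(3)
  expect_error(solveShmr(S0, S0 * 0,
    SolverConfig(objectiveFamily = "regression_fit")), "correlation_fit")
  expect_error(solveRegressionFamily(matrix(rnorm(12), 4, 3), NULL,
    SolverConfig()), "regression_fit")
  expect_error(solveRegressionFamily(matrix(rnorm(12), 4, 3), NULL,
    SolverConfig(beta = 0.1, objectiveFamily = "regression_fit")),
    "Laplacian")
})

test_that("constructSdbfn reduces, sparsifies and truncates as expected", {
  set.seed(46)
  ts <- RoiTimeSeries(matrix(rnorm(60 * 10), 60, 10), "s", 1L)
  spec <- WindowSpec(30, 15)
  pc <- pearsonDynamicNetwork(ts, spec)
  # unregularized: identical to the Pearson network
  plain <- constructSdbfn(ts, spec, 3, SolverConfig(0, 0))
  for (k in seq_along(networkMatrices(pc)))
    expect_equal(networkMatrices(plain)[[k]], networkMatrices(pc)[[k]],
                 tolerance = 1e-12)
  # lambda >= 2 max|S0|: every off-diagonal entry dies
  dead <- constructSdbfn(ts, spec, 3, SolverConfig(2.5, 0))
  for (W in networkMatrices(dead))
    expect_true(all(W[upper.tri(W)] == 0))
  # operating point: strictly sparser than the dense PC network
  sp <- constructSdbfn(ts, spec, 7, SolverConfig(2^-4, 2^-3))
  frac <- mean(vapply(networkMatrices(sp),
                      function(W) mean(W[upper.tri(W)] != 0), numeric(1)))
  expect_lt(frac, 1)
  expect_gt(frac, 0)
})
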