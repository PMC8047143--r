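#' @include AllClasses.R hypergraph.R windowing.R
NULL

#' Elementwise soft threshold
#'
#' The proximal operator of the L1 norm: sgn(m) * max(|m| - t, 0) applied
#' to every element.
#'
#' @param M numeric matrix (or vector).
#' @param t nonnegative threshold.
#' @return Object of the same shape.
#' @examples
#' softThreshold(matrix(c(0.8, -0.1), 1), 0.25)  # 0.55, 0
#' @export
softThreshold <- function(M, t) {
  if (length(t) != 1L || is.na(t) || t < 0)
    stop("invalid threshold: t must be a single nonnegative number",
         call. = FALSE)
  sign(M) * pmax(abs(M) - t, 0)
}

#' SHMR objective value
#'
#' ||W - S0||_F^2 + lambda ||W||_1 + beta tr(W^T L^h W): Frobenius fit to
#' the windowed Pearson matrix S0, L1 sparsity, and hyper-graph manifold
#' smoothness.
#'
#' @param W candidate network matrix.
#' @param S0 windowed Pearson correlation matrix.
#' @param Lh hyper-graph Laplacian.
#' @param lam nonnegative L1 weight.
#' @param beta nonnegative manifold weight.
#' @return Scalar objective value.
#' @export
shmrObjective <- function(W, S0, Lh, lam, beta) {
  stopifnot(all(dim(W) == dim(S0)), all(dim(Lh) == dim(W)))
  sum((W - S0)^2) + lam * sum(abs(W)) + beta * sum(W * (Lh %*% W))
}

# Largest eigenvalue of a symmetric matrix (guarded at 0 for safety).
symLambdaMax <- function(M) {
  if (all(M == 0)) return(0)
  max(0, eigen((M + t(M)) / 2, symmetric = TRUE,
               only.values = TRUE)$values[1L])
}

# Shared proximal-gradient loop. gradFn(W) returns the gradient of the
# smooth part; smoothFn(W) its value; proxExtra(W) an optional projection
# applied after the soft threshold (used for the zero-diagonal constraint
# of the regression family).
proxGradLoop <- function(W0, gradFn, smoothFn, lam, alpha, thr, maxIter,
                         tol, proxExtra = identity) {
  W <- W0
  obj <- smoothFn(W) + lam * sum(abs(W))
  trace <- numeric(maxIter + 1L)
  trace[1L] <- obj
  iters <- 0L
  converged <- FALSE
  for (m in seq_len(maxIter)) {
    W <- proxExtra(softThreshold(W - alpha * gradFn(W), thr))
    newObj <- smoothFn(W) + lam * sum(abs(W))
    if (!is.finite(newObj))
      stop("divergence: objective became non-finite (step size too large?)",
           call. = FALSE)
    trace[m + 1L] <- newObj
    iters <- m
    if (abs(obj - newObj) <= tol * max(1, abs(obj))) {
      converged <- TRUE
      obj <- newObj
      break
    }
    obj <- newObj
  }
  list(W = W, trace = trace[seq_len(iters + 1L)], iters = iters,
       converged = converged)
}

#' Solve the SHMR problem for one window
#'
#' Minimizes the sparse hyper-graph-manifold-regularized fit to a windowed
#' Pearson matrix by proximal gradient descent: a gradient step on the
#' smooth part, whose gradient is 2 (W - S0) + beta L^h W, followed by an
#' elementwise soft threshold, starting from W = S0 (the unregularized
#' optimum). The returned matrix is symmetrized, (W + t(W)) / 2. With
#' lam = 0 this is the HMR estimator; with lam = beta = 0 it returns S0
#' unchanged.
#'
#' Under `stepRule = "lipschitz"` the constant step 1 / (2 + beta *
#' lambda_max(L^h)) is used and the recorded objective trace is
#' non-increasing. The trace records the composite value the iteration
#' minimizes, in which the manifold term enters as (beta / 2)
#' tr(W^T L^h W) — the convention implied by the gradient rule above (see
#' the methods vignette).
#'
#' @param S0 symmetric P x P Pearson matrix.
#' @param Lh symmetric PSD hyper-graph Laplacian.
#' @param cfg a [SolverConfig-class] with `objectiveFamily =
#'   "correlation_fit"`.
#' @return A [SolveResult-class].
#' @examples
#' S0 <- cor(matrix(rnorm(200), 20, 10))
#' hg <- buildHypergraph(S0, k = 3)
#' res <- solveShmr(S0, laplacianMatrix(hg), SolverConfig(2^-4, 2^-3))
#' mean(res@WStar[upper.tri(S0)] == 0)  # sparsity
#' @export
solveShmr <- function(S0, Lh, cfg = SolverConfig()) {
  stopifnot(is(cfg, "SolverConfig"))
  if (cfg@objectiveFamily != "correlation_fit")
    stop("solveShmr requires objectiveFamily = 'correlation_fit'",
         call. = FALSE)
  S0 <- as.matrix(S0)
  Lh <- as.matrix(Lh)
  stopifnot(all(dim(S0) == dim(Lh)))
  beta <- cfg@beta
  lam <- cfg@lam
  alpha <- if (cfg@stepRule == "lipschitz") {
    1 / (2 + beta * symLambdaMax(Lh))
  } else cfg@fixedStep
  thr <- if (cfg@thresholdScaling == "step_scaled") alpha * lam else lam
  fit <- proxGradLoop(
    W0 = S0,
    gradFn = function(W) 2 * (W - S0) + beta * (Lh %*% W),
    smoothFn = function(W) sum((W - S0)^2) +
      (beta / 2) * sum(W * (Lh %*% W)),
    lam = lam, alpha = alpha, thr = thr,
    maxIter = cfg@maxIter, tol = cfg@tol)
  new("SolveResult", WStar = (fit$W + t(fit$W)) / 2,
      objectiveTrace = fit$trace, iterationsUsed = fit$iters,
      converged = fit$converged)
}

#' Normalized simple-graph Laplacian of a correlation network
#'
#' L = I - D^{-1/2} |S| D^{-1/2} with D_ii = sum_j |S_ij|. Absolute values
#' are taken because Pearson matrices carry negative entries and the
#' degree normalization must stay real.
#'
#' @param S symmetric correlation matrix.
#' @return Symmetric PSD Laplacian of the same size.
#' @examples
#' simpleGraphLaplacian(diag(3))  # zero matrix
#' @export
simpleGraphLaplacian <- function(S) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == ncol(S))
  A <- abs(S)
  d <- rowSums(A)
  if (any(d == 0))
    stop(sprintf("degenerate graph: zero total weight at vertex %s",
                 paste(which(d == 0), collapse = ", ")), call. = FALSE)
  L <- diag(nrow(S)) - A / sqrt(d %o% d)
  (L + t(L)) / 2
}

#' Solve the self-regression network family (SR / MR / SMR)
#'
#' Minimizes ||X - X W||_F^2 + lam ||W||_1 + beta tr(W^T L W) by proximal
#' gradient descent with the gradient rule 2 X^T (X W - X) + beta L W,
#' starting from W = 0 and clamping the diagonal of W to zero after every
#' step (without the clamp, W = I is a trivial optimum of the fit term).
#' lam = 0 gives the manifold-regularized (MR) estimator, beta = 0 the
#' sparse-representation (SR) estimator, both positive the SMR estimator.
#' The returned matrix is symmetrized.
#'
#' As in [solveShmr()], the recorded objective trace uses the (beta / 2)
#' manifold convention consistent with the gradient rule, and is
#' non-increasing under the Lipschitz step 1 / (2 lambda_max(X^T X) +
#' beta lambda_max(L)).
#'
#' @param X standardized window matrix (width x P).
#' @param L simple-graph Laplacian, or NULL when beta = 0.
#' @param cfg a [SolverConfig-class] with `objectiveFamily =
#'   "regression_fit"`.
#' @return A [SolveResult-class].
#' @export
solveRegressionFamily <- function(X, L = NULL,
                                  cfg = SolverConfig(
                                    objectiveFamily = "regression_fit")) {
  stopifnot(is(cfg, "SolverConfig"))
  if (cfg@objectiveFamily != "regression_fit")
    stop("solveRegressionFamily requires objectiveFamily = 'regression_fit'",
         call. = FALSE)
  X <- as.matrix(X)
  P <- ncol(X)
  beta <- cfg@beta
  lam <- cfg@lam
  if (beta > 0 && is.null(L))
    stop("a Laplacian is required when beta > 0", call. = FALSE)
  if (is.null(L)) L <- matrix(0, P, P) else L <- as.matrix(L)
  XtX <- crossprod(X)
  alpha <- if (cfg@stepRule == "lipschitz") {
    1 / (2 * symLambdaMax(XtX) + beta * symLambdaMax(L))
  } else cfg@fixedStep
  thr <- if (cfg@thresholdScaling == "step_scaled") alpha * lam else lam
  zeroDiag <- function(W) { diag(W) <- 0; W }
  fit <- proxGradLoop(
    W0 = matrix(0, P, P),
    gradFn = function(W) 2 * (XtX %*% W - XtX) + beta * (L %*% W),
    smoothFn = function(W) sum((X - X %*% W)^2) +
      (beta / 2) * sum(W * (L %*% W)),
    lam = lam, alpha = alpha, thr = thr,
    maxIter = cfg@maxIter, tol = cfg@tol, proxExtra = zeroDiag)
  new("SolveResult", WStar = (fit$W + t(fit$W)) / 2,
      objectiveTrace = fit$trace, iterationsUsed = fit$iters,
      converged = fit$converged)
}

#' Construct a sparse dynamic network (SHMR / HMR) for one subject
#'
#' Per window: Pearson correlation matrix, KNN hyper-graph on its
#' connectivity profiles, hyper-graph Laplacian, then the SHMR solve. One
#' hyper-graph per window by default; `hypergraphScope = "mean"` builds a
#' single hyper-graph from the mean Pearson network and shares its
#' Laplacian across windows.
#'
#' @param ts a [RoiTimeSeries-class].
#' @param spec a [WindowSpec-class].
#' @param k hyper-edge neighborhood size.
#' @param cfg a [SolverConfig-class] (correlation_fit family).
#' @param hypergraphScope "per_window" or "mean".
#' @param edgeWeights "unit" or "gaussian".
#' @return A [DynamicNetwork-class] of K symmetrized sparse matrices.
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(600), 60, 10), "s01", 1L)
#' net <- constructSdbfn(ts, WindowSpec(30, 15), k = 3,
#'                       SolverConfig(2^-4, 2^-3))
#' @export
constructSdbfn <- function(ts, spec, k, cfg = SolverConfig(),
                           hypergraphScope = c("per_window", "mean"),
                           edgeWeights = c("unit", "gaussian")) {
  hypergraphScope <- match.arg(hypergraphScope)
  edgeWeights <- match.arg(edgeWeights)
  pc <- pearsonDynamicNetwork(ts, spec)
  mats <- networkMatrices(pc)
  sharedLh <- NULL
  if (hypergraphScope == "mean") {
    meanW <- Reduce(`+`, mats) / length(mats)
    sharedLh <- laplacianMatrix(buildHypergraph(meanW, k, edgeWeights))
  }
  out <- vector("list", length(mats))
  for (kk in seq_along(mats)) {
    S0 <- mats[[kk]]
    Lh <- if (is.null(sharedLh)) {
      tryCatch(laplacianMatrix(buildHypergraph(S0, k, edgeWeights)),
               error = function(e) stop(sprintf(
                 "window %d: %s", kk, conditionMessage(e)), call. = FALSE))
    } else sharedLh
    res <- tryCatch(solveShmr(S0, Lh, cfg),
                    error = function(e) stop(sprintf(
                      "window %d: %s", kk, conditionMessage(e)),
                      call. = FALSE))
    out[[kk]] <- res@WStar
  }
  new("DynamicNetwork", matrices = out, windowSpec = spec,
      subjectId = ts@subjectId)
}
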