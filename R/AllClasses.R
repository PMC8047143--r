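#' @import methods
NULL

#' Sliding-window specification
#'
#' Holds the width and step (both in time points) of the sliding window used
#' to cut a full ROI time series into overlapping sub-series.
#'
#' @slot width positive integer, window width in time points.
#' @slot step positive integer, offset between consecutive window starts.
#'
#' @seealso [countWindows()], [pearsonDynamicNetwork()]
#' @export
setClass("WindowSpec",
  representation(width = "integer", step = "integer"))

setValidity("WindowSpec", function(object) {
  msg <- character()
  if (length(object@width) != 1L || is.na(object@width) || object@width < 1L)
    msg <- c(msg, "'width' must be a single positive integer")
  if (length(object@step) != 1L || is.na(object@step) || object@step < 1L)
    msg <- c(msg, "'step' must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a WindowSpec
#'
#' @param width window width in time points (positive integer).
#' @param step step size in time points (positive integer, default 1).
#' @return A [WindowSpec-class] object.
#' @examples
#' WindowSpec(50, 1)
#' @export
WindowSpec <- function(width, step = 1L) {
  new("WindowSpec", width = as.integer(width), step = as.integer(step))
}

#' One subject's ROI time-series matrix
#'
#' A Q x P real matrix of BOLD-like signals (rows = time points, columns =
#' regions) together with a subject identifier and a binary group label
#' (1 = positive / patient-like, 0 = negative / control-like).
#'
#' @slot data numeric matrix, Q time points x P regions, no missing values.
#' @slot subjectId character scalar.
#' @slot label integer scalar in \{0, 1\} (NA allowed for unlabelled data).
#'
#' @export
setClass("RoiTimeSeries",
  representation(data = "matrix", subjectId = "character", label = "integer"))

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  d <- object@data
  if (!is.numeric(d)) msg <- c(msg, "'data' must be a numeric matrix")
  if (nrow(d) < 2L || ncol(d) < 2L)
    msg <- c(msg, "'data' needs at least 2 time points and 2 regions")
  if (anyNA(d) || any(!is.finite(d)))
    msg <- c(msg, "'data' must be finite with no missing values")
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "'subjectId' must be a single string")
  if (length(object@label) != 1L ||
      (!is.na(object@label) && !object@label %in% c(0L, 1L)))
    msg <- c(msg, "'label' must be 0, 1 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a RoiTimeSeries
#'
#' @param data numeric matrix, rows = time points, columns = regions.
#' @param subjectId subject identifier string.
#' @param label binary group label (1 = positive class, 0 = negative class,
#'   NA if unknown).
#' @return A [RoiTimeSeries-class] object.
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(200), 50, 4), "s01", 1L)
#' @export
RoiTimeSeries <- function(data, subjectId = "subject", label = NA_integer_) {
  new("RoiTimeSeries", data = as.matrix(data),
      subjectId = as.character(subjectId), label = as.integer(label))
}

#' Dynamic brain functional network
#'
#' An ordered list of K symmetric P x P connectivity matrices for one
#' subject, one matrix per sliding window.
#'
#' @slot matrices list of K symmetric numeric P x P matrices.
#' @slot windowSpec the [WindowSpec-class] that produced them.
#' @slot subjectId character scalar.
#'
#' @export
setClass("DynamicNetwork",
  representation(matrices = "list", windowSpec = "WindowSpec",
                 subjectId = "character"))

setValidity("DynamicNetwork", function(object) {
  msg <- character()
  if (length(object@matrices) < 1L)
    msg <- c(msg, "'matrices' must contain at least one matrix")
  P <- ncol(object@matrices[[1L]])
  for (k in seq_along(object@matrices)) {
    M <- object@matrices[[k]]
    if (!is.matrix(M) || nrow(M) != P || ncol(M) != P) {
      msg <- c(msg, sprintf("matrix %d is not %d x %d", k, P, P))
      next
    }
    if (any(!is.finite(M)))
      msg <- c(msg, sprintf("matrix %d has non-finite entries", k))
    else if (max(abs(M - t(M))) > 1e-10)
      msg <- c(msg, sprintf("matrix %d is not symmetric (tol 1e-10)", k))
  }
  if (length(msg)) msg else TRUE
})

#' Hyper-graph over brain regions
#'
#' A KNN hyper-graph with one hyper-edge per region (so M = P): the binary
#' incidence matrix H (vertices x edges), the hyper-edge weights a(e_b), the
#' vertex degrees d(v), the edge degrees delta(e_b), and the normalized
#' hyper-graph Laplacian L^h = I - D_v^{-1/2} H A D_e^{-1} H^T D_v^{-1/2}.
#'
#' @slot incidence binary matrix, vertices x hyper-edges.
#' @slot edgeWeights positive numeric vector, one weight per hyper-edge.
#' @slot vertexDegrees numeric vector d(v) = sum_b a(e_b) H(v, e_b).
#' @slot edgeDegrees numeric vector delta(e_b) = sum_v H(v, e_b).
#' @slot laplacian symmetric PSD numeric matrix.
#'
#' @export
setClass("HyperGraph",
  representation(incidence = "matrix", edgeWeights = "numeric",
                 vertexDegrees = "numeric", edgeDegrees = "numeric",
                 laplacian = "matrix"))

setValidity("HyperGraph", function(object) {
  msg <- character()
  H <- object@incidence
  if (!all(H %in% c(0, 1))) msg <- c(msg, "incidence entries must be 0/1")
  if (any(object@edgeWeights <= 0))
    msg <- c(msg, "edge weights must be positive")
  if (length(object@edgeWeights) != ncol(H))
    msg <- c(msg, "one weight per hyper-edge required")
  if (any(object@vertexDegrees <= 0))
    msg <- c(msg, "every vertex must have positive degree")
  if (length(msg)) msg else TRUE
})

#' Solver configuration for the sparse-network optimizers
#'
#' Settings for the proximal-gradient solvers: the L1 weight lambda, the
#' manifold weight beta, the iteration budget, the stopping tolerance on the
#' relative objective change, the step-size rule and the scaling convention
#' for the soft threshold.
#'
#' @slot lam nonnegative L1 penalty weight (lambda).
#' @slot beta nonnegative manifold penalty weight.
#' @slot maxIter positive integer iteration cap.
#' @slot tol positive relative-objective stopping tolerance.
#' @slot stepRule "lipschitz" (constant step from the gradient's Lipschitz
#'   bound, guarantees descent) or "fixed".
#' @slot fixedStep positive step used when `stepRule = "fixed"`.
#' @slot thresholdScaling "step_scaled" (threshold = step x lambda, the
#'   proximal operator of the scaled L1 term) or "literal" (threshold =
#'   lambda as printed in the source soft-threshold rule).
#' @slot objectiveFamily "correlation_fit" (fit to the windowed Pearson
#'   matrix; SHMR/HMR) or "regression_fit" (self-regression of the windowed
#'   time series; SR/MR/SMR).
#'
#' @export
setClass("SolverConfig",
  representation(lam = "numeric", beta = "numeric", maxIter = "integer",
                 tol = "numeric", stepRule = "character",
                 fixedStep = "numeric", thresholdScaling = "character",
                 objectiveFamily = "character"))

setValidity("SolverConfig", function(object) {
  msg <- character()
  if (object@lam < 0) msg <- c(msg, "'lam' must be >= 0")
  if (object@beta < 0) msg <- c(msg, "'beta' must be >= 0")
  if (object@maxIter < 1L) msg <- c(msg, "'maxIter' must be >= 1")
  if (object@tol <= 0) msg <- c(msg, "'tol' must be > 0")
  if (!object@stepRule %in% c("lipschitz", "fixed"))
    msg <- c(msg, "'stepRule' must be 'lipschitz' or 'fixed'")
  if (object@stepRule == "fixed" && object@fixedStep <= 0)
    msg <- c(msg, "'fixedStep' must be > 0 when stepRule = 'fixed'")
  if (!object@thresholdScaling %in% c("step_scaled", "literal"))
    msg <- c(msg, "'thresholdScaling' must be 'step_scaled' or 'literal'")
  if (!object@objectiveFamily %in% c("correlation_fit", "regression_fit"))
    msg <- c(msg,
      "'objectiveFamily' must be 'correlation_fit' or 'regression_fit'")
  if (length(msg)) msg else TRUE
})

#' Construct a SolverConfig
#'
#' @param lam nonnegative L1 weight (default 2^-4, the operating point used
#'   throughout the package).
#' @param beta nonnegative manifold weight (default 2^-3).
#' @param maxIter iteration cap (default 500).
#' @param tol relative-objective stopping tolerance (default 1e-6).
#' @param stepRule "lipschitz" or "fixed".
#' @param fixedStep step size when `stepRule = "fixed"`.
#' @param thresholdScaling "step_scaled" or "literal".
#' @param objectiveFamily "correlation_fit" or "regression_fit".
#' @return A [SolverConfig-class] object.
#' @examples
#' SolverConfig(lam = 2^-4, beta = 2^-3)
#' @export
SolverConfig <- function(lam = 2^-4, beta = 2^-3, maxIter = 500L,
                         tol = 1e-6, stepRule = c("lipschitz", "fixed"),
                         fixedStep = 1e-2,
                         thresholdScaling = c("step_scaled", "literal"),
                         objectiveFamily = c("correlation_fit",
                                             "regression_fit")) {
  new("SolverConfig", lam = as.numeric(lam), beta = as.numeric(beta),
      maxIter = as.integer(maxIter), tol = as.numeric(tol),
      stepRule = match.arg(stepRule), fixedStep = as.numeric(fixedStep),
      thresholdScaling = match.arg(thresholdScaling),
      objectiveFamily = match.arg(objectiveFamily))
}

#' Result of one sparse-network solve
#'
#' @slot WStar the symmetrized solution (W + t(W)) / 2.
#' @slot objectiveTrace objective value at the initial point and after each
#'   iteration (the composite objective the iteration minimizes; see the
#'   methods vignette for the manifold-term convention).
#' @slot iterationsUsed number of proximal-gradient iterations performed.
#' @slot converged TRUE if the relative objective change fell below tol.
#'
#' @export
setClass("SolveResult",
  representation(WStar = "matrix", objectiveTrace = "numeric",
                 iterationsUsed = "integer", converged = "logical"))

#' Per-subject feature vector
#'
#' Weighted local clustering coefficients (one per region under the "mean"
#' aggregation, K x P under "concat"), with subject id and label.
#'
#' @slot values numeric vector of coefficients in \[0, 1\].
#' @slot subjectId character scalar.
#' @slot label integer scalar in \{0, 1\} or NA.
#'
#' @export
setClass("FeatureVector",
  representation(values = "numeric", subjectId = "character",
                 label = "integer"))

#' Synthetic-cohort specification
#'
#' Describes a two-group cohort of ROI time series with modular, block-
#' constant correlation structure: `rhoWithin` inside modules, `rhoBetween`
#' between them; the positive group has `rhoWithin - effectDelta` inside the
#' modules listed in `affectedModules` (correlation attenuation, the
#' "functional disconnection" direction). Temporal structure is AR(1) with
#' coefficient `arCoeff`, plus white observation noise of sd `noiseSd`.
#'
#' @slot nPos,nNeg integer subjects per group.
#' @slot P,Q integer numbers of regions and time points.
#' @slot modules list of integer vectors partitioning (a subset of) 1:P.
#' @slot rhoWithin,rhoBetween baseline correlations.
#' @slot effectDelta correlation reduction in the affected modules of the
#'   positive group.
#' @slot affectedModules integer indices into `modules`.
#' @slot arCoeff AR(1) coefficient in \[0, 1).
#' @slot noiseSd nonnegative white-noise sd.
#' @slot seed integer master seed.
#'
#' @export
setClass("CohortSpec",
  representation(nPos = "integer", nNeg = "integer", P = "integer",
                 Q = "integer", modules = "list", rhoWithin = "numeric",
                 rhoBetween = "numeric", effectDelta = "numeric",
                 affectedModules = "integer", arCoeff = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPos < 0L || object@nNeg < 0L ||
      object@nPos + object@nNeg < 1L)
    msg <- c(msg, "need nonnegative group sizes with at least one subject")
  if (object@P < 2L || object@Q < 2L)
    msg <- c(msg, "need P >= 2 regions and Q >= 2 time points")
  idx <- unlist(object@modules)
  if (length(idx) && (anyDuplicated(idx) || any(idx < 1L) ||
                      any(idx > object@P)))
    msg <- c(msg, "'modules' must be disjoint subsets of 1:P")
  if (any(object@affectedModules < 1L) ||
      any(object@affectedModules > length(object@modules)))
    msg <- c(msg, "'affectedModules' must index into 'modules'")
  if (object@rhoWithin < 0 || object@rhoWithin >= 1)
    msg <- c(msg, "'rhoWithin' must be in [0, 1)")
  if (object@rhoBetween < 0 || object@rhoBetween > object@rhoWithin)
    msg <- c(msg, "'rhoBetween' must be in [0, rhoWithin]")
  if (object@effectDelta < 0 || object@effectDelta > object@rhoWithin)
    msg <- c(msg, "'effectDelta' must be in [0, rhoWithin]")
  if (object@arCoeff < 0 || object@arCoeff >= 1)
    msg <- c(msg, "'arCoeff' must be in [0, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' Defaults describe the study conditions used throughout the package's
#' simulations: two groups of 40 subjects, 30 regions in 6 modules of 5,
#' 120 time points, baseline correlations 0.6 (within) / 0.1 (between),
#' a correlation attenuation of 0.3 in the first two modules of the positive
#' group, AR(1) coefficient 0.3 and observation-noise sd 0.5.
#'
#' @param nPos,nNeg subjects per group.
#' @param P,Q numbers of regions and time points.
#' @param modules list of integer vectors (disjoint region blocks).
#' @param rhoWithin,rhoBetween baseline correlations.
#' @param effectDelta correlation reduction in affected modules (positive
#'   group); 0 gives two identical groups (null cohort).
#' @param affectedModules indices into `modules`.
#' @param arCoeff AR(1) temporal autocorrelation coefficient.
#' @param noiseSd white observation-noise sd.
#' @param seed integer master seed; all randomness derives from it.
#' @return A [CohortSpec-class] object.
#' @examples
#' spec <- CohortSpec(nPos = 5, nNeg = 5, seed = 7)
#' @export
CohortSpec <- function(nPos = 40L, nNeg = 40L, P = 30L, Q = 120L,
                       modules = split(seq_len(P),
                                       rep(seq_len(max(1L, P %/% 5L)),
                                           each = 5L, length.out = P)),
                       rhoWithin = 0.6, rhoBetween = 0.1,
                       effectDelta = 0.3, affectedModules = c(1L, 2L),
                       arCoeff = 0.3, noiseSd = 0.5, seed = 1L) {
  new("CohortSpec", nPos = as.integer(nPos), nNeg = as.integer(nNeg),
      P = as.integer(P), Q = as.integer(Q),
      modules = lapply(modules, as.integer),
      rhoWithin = as.numeric(rhoWithin), rhoBetween = as.numeric(rhoBetween),
      effectDelta = as.numeric(effectDelta),
      affectedModules = as.integer(affectedModules),
      arCoeff = as.numeric(arCoeff), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' Cross-validated classification result
#'
#' Aggregate and per-repetition accuracy (ACC), sensitivity (SEN),
#' specificity (SPE) and area under the ROC curve (AUC) from repeated
#' stratified k-fold cross-validation, together with the number of features
#' passing the t-test in every training fold.
#'
#' @slot accMean,accSd,senMean,senSd,speMean,speSd,aucMean,aucSd numeric
#'   summaries over repetitions (proportions in \[0, 1\], not percent).
#' @slot perRepetition data.frame with one row per repetition (columns
#'   rep, acc, sen, spe, auc).
#' @slot selectedCounts integer vector, features selected per training fold
#'   (reps x folds entries).
#'
#' @export
setClass("CohortResult",
  representation(accMean = "numeric", accSd = "numeric",
                 senMean = "numeric", senSd = "numeric",
                 speMean = "numeric", speSd = "numeric",
                 aucMean = "numeric", aucSd = "numeric",
                 perRepetition = "data.frame",
                 selectedCounts = "integer"))

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline (network construction
#' method, window geometry, hyper-graph neighborhood size, regularization
#' weights, solver and cross-validation settings). Defaults are the selected
#' operating point of the method: window width 50, step 1, k = 7 neighbors,
#' lambda = 2^-4, beta = 2^-3.
#'
#' @slot method one of "pc", "sr", "mr", "smr", "hmr", "shmr".
#' @slot windowWidth,windowStep sliding-window geometry (time points).
#' @slot kNeighbors KNN hyper-edge size parameter.
#' @slot lam,beta regularization weights (ignored where the method fixes
#'   them: pc uses neither, mr has lam = 0, sr has beta = 0, hmr has
#'   lam = 0).
#' @slot maxIter,tol,stepRule,thresholdScaling solver settings (see
#'   [SolverConfig()]).
#' @slot hypergraphScope "per_window" (one hyper-graph per window) or
#'   "mean" (a single hyper-graph from the mean Pearson network).
#' @slot edgeWeights "unit" or "gaussian" hyper-edge weighting.
#' @slot clusteringMode "onnela" or "literal" (see [localClustering()]).
#' @slot aggregate "mean" or "concat" pooling of per-window features.
#' @slot folds,reps,alpha,cost,nested cross-validation settings (see
#'   [repeatedCV()]).
#' @slot seed integer seed for the cross-validation randomness.
#'
#' @export
setClass("PipelineConfig",
  representation(method = "character", windowWidth = "integer",
                 windowStep = "integer", kNeighbors = "integer",
                 lam = "numeric", beta = "numeric", maxIter = "integer",
                 tol = "numeric", stepRule = "character",
                 thresholdScaling = "character",
                 hypergraphScope = "character", edgeWeights = "character",
                 clusteringMode = "character", aggregate = "character",
                 folds = "integer", reps = "integer", alpha = "numeric",
                 cost = "numeric", nested = "logical", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (!object@method %in% c("pc", "sr", "mr", "smr", "hmr", "shmr"))
    msg <- c(msg, "'method' must be one of pc, sr, mr, smr, hmr, shmr")
  if (object@windowWidth < 2L) msg <- c(msg, "'windowWidth' must be >= 2")
  if (object@windowStep < 1L) msg <- c(msg, "'windowStep' must be >= 1")
  if (object@kNeighbors < 1L) msg <- c(msg, "'kNeighbors' must be >= 1")
  if (object@lam < 0 || object@beta < 0)
    msg <- c(msg, "'lam' and 'beta' must be >= 0")
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "'alpha' must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param method network construction method.
#' @param windowWidth,windowStep sliding-window geometry.
#' @param kNeighbors hyper-edge neighborhood size.
#' @param lam,beta regularization weights.
#' @param maxIter,tol,stepRule,thresholdScaling solver settings.
#' @param hypergraphScope "per_window" or "mean".
#' @param edgeWeights "unit" or "gaussian".
#' @param clusteringMode "onnela" or "literal".
#' @param aggregate "mean" or "concat".
#' @param folds,reps,alpha,cost,nested cross-validation settings.
#' @param seed integer seed.
#' @return A [PipelineConfig-class] object.
#' @examples
#' PipelineConfig(method = "shmr", windowStep = 5L, seed = 11L)
#' @export
PipelineConfig <- function(method = "shmr", windowWidth = 50L,
                           windowStep = 1L, kNeighbors = 7L,
                           lam = 2^-4, beta = 2^-3, maxIter = 500L,
                           tol = 1e-6, stepRule = "lipschitz",
                           thresholdScaling = "step_scaled",
                           hypergraphScope = c("per_window", "mean"),
                           edgeWeights = c("unit", "gaussian"),
                           clusteringMode = c("onnela", "literal"),
                           aggregate = c("mean", "concat"),
                           folds = 10L, reps = 10L, alpha = 0.05,
                           cost = 1, nested = TRUE, seed = 1L) {
  new("PipelineConfig", method = method,
      windowWidth = as.integer(windowWidth),
      windowStep = as.integer(windowStep),
      kNeighbors = as.integer(kNeighbors),
      lam = as.numeric(lam), beta = as.numeric(beta),
      maxIter = as.integer(maxIter), tol = as.numeric(tol),
      stepRule = stepRule, thresholdScaling = thresholdScaling,
      hypergraphScope = match.arg(hypergraphScope),
      edgeWeights = match.arg(edgeWeights),
      clusteringMode = match.arg(clusteringMode),
      aggregate = match.arg(aggregate),
      folds = as.integer(folds), reps = as.integer(reps),
      alpha = as.numeric(alpha), cost = as.numeric(cost),
      nested = as.logical(nested), seed = as.integer(seed))
}
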