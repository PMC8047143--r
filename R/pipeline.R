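#' @include AllClasses.R solvers.R graph_metrics.R classify.R io.R
NULL

# Effective (lam, beta) for each method; pc bypasses the solvers entirely.
methodWeights <- function(config) {
  switch(config@method,
    pc   = c(lam = 0, beta = 0),
    sr   = c(lam = config@lam, beta = 0),
    mr   = c(lam = 0, beta = config@beta),
    smr  = c(lam = config@lam, beta = config@beta),
    hmr  = c(lam = 0, beta = config@beta),
    shmr = c(lam = config@lam, beta = config@beta))
}

#' Construct one subject's network under a pipeline configuration
#'
#' Dispatches on `config@method`: "pc" gives the sliding-window Pearson
#' network; "sr"/"mr"/"smr" solve the self-regression family per window
#' (with the simple-graph Laplacian of the window's Pearson matrix as the
#' manifold when beta > 0); "hmr"/"shmr" solve the hyper-graph-regularized
#' correlation fit ("hmr" is "shmr" with lam = 0).
#'
#' @param ts a [RoiTimeSeries-class].
#' @param config a [PipelineConfig-class].
#' @return A [DynamicNetwork-class].
#' @export
constructNetwork <- function(ts, config) {
  stopifnot(is(ts, "RoiTimeSeries"), is(config, "PipelineConfig"))
  spec <- WindowSpec(config@windowWidth, config@windowStep)
  w <- methodWeights(config)
  if (config@method == "pc")
    return(pearsonDynamicNetwork(ts, spec))
  if (config@method %in% c("hmr", "shmr")) {
    cfg <- SolverConfig(lam = w[["lam"]], beta = w[["beta"]],
                        maxIter = config@maxIter, tol = config@tol,
                        stepRule = config@stepRule,
                        thresholdScaling = config@thresholdScaling,
                        objectiveFamily = "correlation_fit")
    return(constructSdbfn(ts, spec, config@kNeighbors, cfg,
                          hypergraphScope = config@hypergraphScope,
                          edgeWeights = config@edgeWeights))
  }
  # sr / mr / smr: per-window self-regression on the standardized window
  cfg <- SolverConfig(lam = w[["lam"]], beta = w[["beta"]],
                      maxIter = config@maxIter, tol = config@tol,
                      stepRule = config@stepRule,
                      thresholdScaling = config@thresholdScaling,
                      objectiveFamily = "regression_fit")
  X <- tsMatrix(ts)
  starts <- windowStarts(nrow(X), spec)
  mats <- lapply(seq_along(starts), function(k) {
    rows <- starts[k]:(starts[k] + spec@width - 1L)
    Xs <- standardizeWindow(X[rows, , drop = FALSE])
    L <- if (w[["beta"]] > 0) simpleGraphLaplacian(crossprod(Xs)) else NULL
    solveRegressionFamily(Xs, L, cfg)@WStar
  })
  new("DynamicNetwork", matrices = mats, windowSpec = spec,
      subjectId = ts@subjectId)
}

#' Run the full classification pipeline on a cohort
#'
#' Windowing, network construction (per `config@method`), per-subject
#' clustering-coefficient features, then repeated stratified k-fold SVM
#' evaluation. When `outDir` is given, the feature table (CSV), the
#' classification metrics plus the fully resolved configuration (JSON),
#' and optionally every subject's window matrices are written there.
#'
#' @param cohort list of [RoiTimeSeries-class] objects, a list with a
#'   `subjects` element ([sampleCohort()] output), or the path of a
#'   manifest CSV.
#' @param config a [PipelineConfig-class].
#' @param outDir optional output directory.
#' @param writeNetworks also write per-window matrices (default FALSE).
#' @return List with `result` (a [CohortResult-class]), `features`,
#'   `labels`, `networks`, and `config`.
#' @examples
#' cohort <- sampleCohort(CohortSpec(nPos = 12, nNeg = 12, P = 10, Q = 60,
#'                                   modules = list(1:5, 6:10),
#'                                   affectedModules = 1L, seed = 3))
#' cfg <- PipelineConfig(method = "pc", windowWidth = 30L,
#'                       windowStep = 15L, folds = 4L, reps = 2L, seed = 9L)
#' run <- runPipeline(cohort, cfg)
#' run$result
#' @export
runPipeline <- function(cohort, config, outDir = NULL,
                        writeNetworks = FALSE) {
  stopifnot(is(config, "PipelineConfig"))
  if (is.character(cohort)) cohort <- readCohort(cohort)
  if (is.list(cohort) && !is.null(cohort$subjects))
    cohort <- cohort$subjects
  labels <- vapply(cohort, subjectLabel, integer(1))
  nets <- lapply(cohort, function(s)
    tryCatch(constructNetwork(s, config),
             error = function(e) stop(sprintf(
               "subject %s: %s", subjectId(s), conditionMessage(e)),
               call. = FALSE)))
  feat <- cohortFeatures(nets, labels, aggregate = config@aggregate,
                         mode = config@clusteringMode)
  result <- repeatedCV(feat$features, feat$labels, folds = config@folds,
                       reps = config@reps, seed = config@seed,
                       alpha = config@alpha, cost = config@cost,
                       nested = config@nested)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      data.frame(subject_id = rownames(feat$features), feat$features,
                 label = feat$labels, check.names = FALSE),
      file.path(outDir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(config = configAsList(config),
           metrics = as.list(metricSummary(result)),
           per_repetition = result@perRepetition,
           selected_counts = result@selectedCounts),
      file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    if (writeNetworks)
      for (net in nets)
        writeDynamicNetwork(net, file.path(outDir, "networks"))
  }
  list(result = result, features = feat$features, labels = feat$labels,
       networks = nets, config = config)
}

# Full resolved configuration as a plain named list (for JSON provenance).
configAsList <- function(config) {
  slots <- slotNames(config)
  out <- lapply(slots, function(s) slot(config, s))
  names(out) <- slots
  out
}

# Overwrite config slots named in `row` (a one-row data.frame or list).
modifyConfig <- function(config, row) {
  for (nm in names(row)) {
    if (!nm %in% slotNames(config))
      stop(sprintf("unknown pipeline parameter '%s'", nm), call. = FALSE)
    slot(config, nm) <- as(row[[nm]], class(slot(config, nm)))
  }
  validObject(config)
  config
}

#' Sweep a parameter grid over the pipeline
#'
#' Runs [runPipeline()] once per row of `grid` (columns name
#' [PipelineConfig-class] slots, e.g. `lam`, `beta`, `kNeighbors`,
#' `windowWidth`) and collects the classification metrics into one table
#' mirroring a parameter-sensitivity study. An empty grid returns an empty
#' table.
#'
#' @param cohort as in [runPipeline()].
#' @param config the base [PipelineConfig-class].
#' @param grid data.frame of parameter overrides, one row per grid point.
#' @param outFile optional CSV path for the result table.
#' @return data.frame with the grid columns plus acc/sen/spe/auc means and
#'   standard deviations (proportions in \[0, 1\]).
#' @export
sweepGrid <- function(cohort, config, grid, outFile = NULL) {
  metricCols <- c("acc", "acc_sd", "sen", "sen_sd", "spe", "spe_sd",
                  "auc", "auc_sd")
  if (nrow(grid) == 0L) {
    out <- cbind(grid, as.data.frame(
      matrix(numeric(0), 0L, length(metricCols),
             dimnames = list(NULL, metricCols))))
    if (!is.null(outFile)) utils::write.csv(out, outFile, row.names = FALSE)
    return(out)
  }
  if (is.character(cohort)) cohort <- readCohort(cohort)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- modifyConfig(config, grid[i, , drop = FALSE])
    res <- runPipeline(cohort, cfg)$result
    cbind(grid[i, , drop = FALSE],
          as.data.frame(as.list(metricSummary(res))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(outFile)) utils::write.csv(out, outFile, row.names = FALSE)
  out
}
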