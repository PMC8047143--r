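#' @include AllClasses.R
NULL

#' Accessors for sdbfn objects
#'
#' Small accessor generics used across the package's S4 classes: the raw
#' data matrix of a time series, subject id and label, the list of
#' per-window connectivity matrices, and the hyper-graph Laplacian.
#'
#' @param x an sdbfn S4 object.
#' @return The slot contents (see the individual class pages).
#' @name sdbfn-accessors
NULL

#' @rdname sdbfn-accessors
#' @export
setGeneric("tsMatrix", function(x) standardGeneric("tsMatrix"))

#' @rdname sdbfn-accessors
#' @export
setMethod("tsMatrix", "RoiTimeSeries", function(x) x@data)

#' @rdname sdbfn-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname sdbfn-accessors
#' @export
setMethod("subjectId", "RoiTimeSeries", function(x) x@subjectId)

#' @rdname sdbfn-accessors
#' @export
setMethod("subjectId", "DynamicNetwork", function(x) x@subjectId)

#' @rdname sdbfn-accessors
#' @export
setMethod("subjectId", "FeatureVector", function(x) x@subjectId)

#' @rdname sdbfn-accessors
#' @export
setGeneric("subjectLabel", function(x) standardGeneric("subjectLabel"))

#' @rdname sdbfn-accessors
#' @export
setMethod("subjectLabel", "RoiTimeSeries", function(x) x@label)

#' @rdname sdbfn-accessors
#' @export
setMethod("subjectLabel", "FeatureVector", function(x) x@label)

#' @rdname sdbfn-accessors
#' @export
setGeneric("networkMatrices", function(x) standardGeneric("networkMatrices"))

#' @rdname sdbfn-accessors
#' @export
setMethod("networkMatrices", "DynamicNetwork", function(x) x@matrices)

#' @rdname sdbfn-accessors
#' @export
setGeneric("laplacianMatrix", function(x) standardGeneric("laplacianMatrix"))

#' @rdname sdbfn-accessors
#' @export
setMethod("laplacianMatrix", "HyperGraph", function(x) x@laplacian)

#' @rdname sdbfn-accessors
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))

#' @rdname sdbfn-accessors
#' @export
setMethod("incidenceMatrix", "HyperGraph", function(x) x@incidence)

#' @rdname sdbfn-accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname sdbfn-accessors
#' @export
setMethod("featureValues", "FeatureVector", function(x) x@values)

#' Summary metric accessor
#'
#' Returns the aggregate classification metrics of a [CohortResult-class]
#' as a named numeric vector (proportions, not percent): acc, acc_sd, sen,
#' sen_sd, spe, spe_sd, auc, auc_sd.
#'
#' @param x a [CohortResult-class].
#' @return Named numeric vector of length 8.
#' @export
setGeneric("metricSummary", function(x) standardGeneric("metricSummary"))

#' @rdname metricSummary
#' @export
setMethod("metricSummary", "CohortResult", function(x) {
  c(acc = x@accMean, acc_sd = x@accSd, sen = x@senMean, sen_sd = x@senSd,
    spe = x@speMean, spe_sd = x@speSd, auc = x@aucMean, auc_sd = x@aucSd)
})

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec: width %d, step %d (time points)\n",
              object@width, object@step))
})

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries '%s': %d time points x %d regions, label %s\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              ifelse(is.na(object@label), "NA",
                     as.character(object@label))))
})

setMethod("show", "DynamicNetwork", function(object) {
  P <- ncol(object@matrices[[1L]])
  cat(sprintf(
    "DynamicNetwork '%s': %d windows of %d x %d (width %d, step %d)\n",
    object@subjectId, length(object@matrices), P, P,
    object@windowSpec@width, object@windowSpec@step))
})

setMethod("show", "HyperGraph", function(object) {
  cat(sprintf(
    "HyperGraph: %d vertices, %d hyper-edges, edge degrees %s\n",
    nrow(object@incidence), ncol(object@incidence),
    paste(range(object@edgeDegrees), collapse = "-")))
})

setMethod("show", "SolveResult", function(object) {
  cat(sprintf(
    "SolveResult: %d x %d, %d iterations, %s (final objective %.6g)\n",
    nrow(object@WStar), ncol(object@WStar), object@iterationsUsed,
    if (object@converged) "converged" else "not converged",
    utils::tail(object@objectiveTrace, 1L)))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    paste0("CohortSpec: %d + %d subjects, %d regions, %d time points,\n",
           "  %d modules, rho %.2f/%.2f, effect delta %.2f on modules {%s},",
           " AR(1) %.2f, noise sd %.2f, seed %d\n"),
    object@nPos, object@nNeg, object@P, object@Q, length(object@modules),
    object@rhoWithin, object@rhoBetween, object@effectDelta,
    paste(object@affectedModules, collapse = ","), object@arCoeff,
    object@noiseSd, object@seed))
})

setMethod("show", "CohortResult", function(object) {
  cat("Repeated stratified cross-validation result\n")
  cat(sprintf("  ACC %6.2f%% +/- %.4f\n", 100 * object@accMean,
              100 * object@accSd))
  cat(sprintf("  SEN %6.2f%% +/- %.4f\n", 100 * object@senMean,
              100 * object@senSd))
  cat(sprintf("  SPE %6.2f%% +/- %.4f\n", 100 * object@speMean,
              100 * object@speSd))
  cat(sprintf("  AUC %6.4f +/- %.4f\n", object@aucMean, object@aucSd))
  cat(sprintf("  (%d repetitions; features selected per fold: median %d)\n",
              nrow(object@perRepetition),
              as.integer(stats::median(object@selectedCounts))))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(
    paste0("PipelineConfig: method %s, window %d/%d, k %d, lambda %.4g, ",
           "beta %.4g,\n  CV %dx%d-fold, alpha %.2f, seed %d\n"),
    object@method, object@windowWidth, object@windowStep,
    object@kNeighbors, object@lam, object@beta, object@reps,
    object@folds, object@alpha, object@seed))
})
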