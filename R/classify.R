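#' @include AllClasses.R
NULL

# Two-sample t-test p-value per feature column. Features with zero variance
# in both groups get NA (no test possible).
ttestPvalues <- function(features, labels, varEqual = TRUE) {
  pos <- labels == 1L
  apply(features, 2L, function(x) {
    if (stats::var(x[pos]) == 0 && stats::var(x[!pos]) == 0)
      return(NA_real_)
    stats::t.test(x[pos], x[!pos], var.equal = varEqual)$p.value
  })
}

#' Two-sample t-test feature selection
#'
#' Marks the features whose two-sample t-test p-value (positive vs negative
#' group) falls strictly below `alpha`. No multiple-testing correction is
#' applied. Equal-variance (pooled) tests by default; `varEqual = FALSE`
#' switches to Welch.
#'
#' @param features numeric matrix, rows = samples, columns = features.
#' @param labels binary integer vector (1 positive, 0 negative).
#' @param alpha significance level (default 0.05); `alpha = 0` selects
#'   nothing.
#' @param varEqual pooled-variance test if TRUE (default).
#' @return Logical mask of length ncol(features). Features with zero
#'   variance in both groups are excluded with a warning.
#' @examples
#' x <- cbind(signal = c(rnorm(10), rnorm(10, 5)), noise = rnorm(20))
#' ttestSelect(x, rep(c(0L, 1L), each = 10))
#' @export
ttestSelect <- function(features, labels, alpha = 0.05, varEqual = TRUE) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    stop("one label per row of 'features' required", call. = FALSE)
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("invalid labels: both classes must be present", call. = FALSE)
  if (nrow(features) < 4L)
    stop("need at least 4 samples for the two-sample t-test",
         call. = FALSE)
  p <- ttestPvalues(features, labels, varEqual)
  if (anyNA(p)) {
    warning(sprintf(
      "feature(s) %s have zero variance in both groups; excluded",
      paste(which(is.na(p)), collapse = ", ")), call. = FALSE)
    p[is.na(p)] <- Inf
  }
  p < alpha
}

#' Classification metrics from confusion counts
#'
#' ACC = (tp + tn) / total, SEN = tp / (tp + fn) (positive-class recall),
#' SPE = tn / (tn + fp) (negative-class recall).
#'
#' @param tp,fn,tn,fp nonnegative confusion counts.
#' @return Named numeric vector with acc, sen, spe and the four counts.
#' @examples
#' evaluateConfusion(35, 10, 40, 6)
#' @export
evaluateConfusion <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0)
    stop("undefined metric: a class is empty", call. = FALSE)
  c(acc = (tp + tn) / sum(counts), sen = tp / (tp + fn),
    spe = tn / (tn + fp), counts)
}

# Stratified fold assignment: permute each class, deal folds cyclically.
stratifiedFolds <- function(labels, folds) {
  assignment <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

# Fit a linear SVM and return oriented decision values (positive score =
# evidence for class 1) plus hard predictions for newx. Features are
# standardized on the training fold (the library default); without it,
# small-scale features make the C-regularized weight vector collapse and
# the classifier degenerates toward one class.
linearSvmScores <- function(trainX, trainY, newX, cost) {
  fit <- e1071::svm(x = trainX, y = factor(trainY, levels = c(0L, 1L)),
                    kernel = "linear", cost = cost, scale = TRUE)
  pred <- stats::predict(fit, newX, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  score <- as.numeric(dv[, 1L])
  # libsvm signs the decision value toward the first-listed class
  if (!startsWith(colnames(dv)[1L], "1")) score <- -score
  list(pred = as.integer(as.character(pred)), score = score)
}

#' Repeated stratified k-fold SVM evaluation
#'
#' The classification protocol of the pipeline: stratified k-fold
#' cross-validation repeated `reps` times; within every training fold a
#' two-sample t-test selects features at level `alpha` (falling back to the
#' single smallest-p feature when none passes), then a linear-kernel SVM
#' (regularization constant `cost`) is fit on the selected features and
#' applied to the held-out fold. Per repetition, out-of-fold predictions
#' are pooled into one confusion matrix for ACC/SEN/SPE, and the pooled
#' decision values give the AUC. Means and standard deviations are taken
#' over repetitions. The positive class (label 1) plays the patient role.
#'
#' With `nested = FALSE` the t-test is instead run once on the full data
#' set before cross-validation (the optimistic unnested protocol some
#' studies use); the nested default is the statistically correct choice.
#'
#' All randomness (fold assignments) derives from `seed`; repeated calls
#' with the same arguments are identical.
#'
#' @param features numeric matrix, rows = subjects.
#' @param labels binary integer vector (1 positive, 0 negative).
#' @param folds number of folds (default 10).
#' @param reps number of repetitions (default 10).
#' @param seed integer seed (required).
#' @param alpha t-test significance level (default 0.05).
#' @param cost SVM regularization constant (default 1).
#' @param nested run feature selection inside each training fold (default
#'   TRUE).
#' @param varEqual pooled-variance t-test if TRUE.
#' @return A [CohortResult-class].
#' @examples
#' x <- rbind(matrix(rnorm(100), 20), matrix(rnorm(100, 2), 20))
#' y <- rep(c(0L, 1L), each = 20)
#' repeatedCV(x, y, folds = 5, reps = 2, seed = 1)
#' @export
repeatedCV <- function(features, labels, folds = 10L, reps = 10L, seed,
                       alpha = 0.05, cost = 1, nested = TRUE,
                       varEqual = TRUE) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (missing(seed)) stop("an explicit 'seed' is required", call. = FALSE)
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos + nNeg != length(labels))
    stop("labels must be 0/1", call. = FALSE)
  if (min(nPos, nNeg) < folds)
    stop(sprintf(
      "invalid cross-validation: smallest class has %d < %d members",
      min(nPos, nNeg), folds), call. = FALSE)

  set.seed(as.integer(seed))
  unnestedMask <- if (!nested) ttestSelect(features, labels, alpha,
                                           varEqual) else NULL
  perRep <- data.frame(rep = seq_len(reps), acc = NA_real_,
                       sen = NA_real_, spe = NA_real_, auc = NA_real_)
  selectedCounts <- integer(0)

  for (r in seq_len(reps)) {
    foldOf <- stratifiedFolds(labels, folds)
    predicted <- integer(length(labels))
    scores <- numeric(length(labels))
    for (f in seq_len(folds)) {
      testIdx <- which(foldOf == f)
      trainIdx <- which(foldOf != f)
      mask <- if (nested) {
        ttestSelect(features[trainIdx, , drop = FALSE], labels[trainIdx],
                    alpha, varEqual)
      } else unnestedMask
      selectedCounts <- c(selectedCounts, sum(mask))
      if (!any(mask)) {
        p <- ttestPvalues(features[trainIdx, , drop = FALSE],
                          labels[trainIdx], varEqual)
        mask[which.min(p)] <- TRUE
      }
      svmOut <- linearSvmScores(features[trainIdx, mask, drop = FALSE],
                                labels[trainIdx],
                                features[testIdx, mask, drop = FALSE],
                                cost)
      predicted[testIdx] <- svmOut$pred
      scores[testIdx] <- svmOut$score
    }
    conf <- evaluateConfusion(
      tp = sum(predicted == 1L & labels == 1L),
      fn = sum(predicted == 0L & labels == 1L),
      tn = sum(predicted == 0L & labels == 0L),
      fp = sum(predicted == 1L & labels == 0L))
    roc <- pROC::roc(response = labels, predictor = scores,
                     levels = c(0L, 1L), direction = "<", quiet = TRUE)
    perRep[r, c("acc", "sen", "spe", "auc")] <-
      c(conf[["acc"]], conf[["sen"]], conf[["spe"]],
        as.numeric(pROC::auc(roc)))
  }

  sdOr0 <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
  new("CohortResult",
      accMean = mean(perRep$acc), accSd = sdOr0(perRep$acc),
      senMean = mean(perRep$sen), senSd = sdOr0(perRep$sen),
      speMean = mean(perRep$spe), speSd = sdOr0(perRep$spe),
      aucMean = mean(perRep$auc), aucSd = sdOr0(perRep$auc),
      perRepetition = perRep, selectedCounts = selectedCounts)
}
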