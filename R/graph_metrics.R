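#' @include AllClasses.R
NULL

#' Weighted local clustering coefficients
#'
#' Per-node clustering of a weighted undirected network. Weights are taken
#' in absolute value, the diagonal is ignored, and weights are normalized
#' by the largest off-diagonal magnitude, so the result is scale invariant
#' and bounded in \[0, 1\].
#'
#' The default `"onnela"` mode is the triangle geometric-mean form:
#' C_i = (2 / (k_i (k_i - 1))) * sum over neighbor pairs j < h of
#' (w_ij w_ih w_jh)^(1/3), with v_i the nonzero neighbors of i and
#' k_i = |v_i|; C_i = 0 when k_i < 2. The `"literal"` mode instead sums
#' the cube-rooted incident edge weights, C_i = 2 sum_{j in v_i}
#' w_ij^(1/3) / (k_i (k_i - 1)), a degree-normalized strength that ignores
#' triangles (kept for comparison; it is not bounded by 1 for k_i = 2).
#'
#' @param W symmetric numeric matrix.
#' @param mode "onnela" (default) or "literal".
#' @return Numeric vector of length P; all zeros for an all-zero matrix.
#' @examples
#' tri <- matrix(1, 3, 3) - diag(3)
#' localClustering(tri)         # 1 1 1
#' star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
#' localClustering(star)        # 0 0 0 0
#' @export
localClustering <- function(W, mode = c("onnela", "literal")) {
  mode <- match.arg(mode)
  W <- as.matrix(W)
  P <- nrow(W)
  stopifnot(ncol(W) == P)
  A <- abs(W)
  diag(A) <- 0
  mx <- max(A)
  if (mx == 0) return(numeric(P))
  A <- A / mx
  k <- rowSums(A > 0)
  denom <- k * (k - 1)
  C <- numeric(P)
  active <- denom > 0
  if (mode == "onnela") {
    Ac <- A^(1 / 3)
    # diag(Ac^3)_i = 2 * sum_{j<h} (w_ij w_jh w_hi)^(1/3)
    tri <- diag(Ac %*% Ac %*% Ac)
    C[active] <- tri[active] / denom[active]
  } else {
    s <- rowSums(A^(1 / 3))
    C[active] <- 2 * s[active] / denom[active]
  }
  C
}

#' Per-subject clustering-coefficient features
#'
#' Computes the weighted local clustering coefficients of every window
#' matrix of a dynamic network and pools them into one feature vector per
#' subject: the elementwise mean over windows (default), or the
#' concatenation of all K per-window vectors.
#'
#' @param net a [DynamicNetwork-class].
#' @param label binary label to attach (1 positive, 0 negative, NA
#'   unknown).
#' @param aggregate "mean" or "concat".
#' @param mode clustering-coefficient mode passed to [localClustering()].
#' @return A [FeatureVector-class] (length P for "mean", K x P for
#'   "concat").
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(300), 60, 5), "s01", 1L)
#' net <- pearsonDynamicNetwork(ts, WindowSpec(30, 10))
#' featureValues(subjectFeatures(net, 1L))
#' @export
subjectFeatures <- function(net, label = NA_integer_,
                            aggregate = c("mean", "concat"),
                            mode = c("onnela", "literal")) {
  aggregate <- match.arg(aggregate)
  mode <- match.arg(mode)
  stopifnot(is(net, "DynamicNetwork"))
  per <- vapply(net@matrices, localClustering,
                numeric(ncol(net@matrices[[1L]])), mode = mode)
  # per is P x K
  values <- if (aggregate == "mean") rowMeans(per) else as.vector(per)
  new("FeatureVector", values = values, subjectId = net@subjectId,
      label = as.integer(label))
}

#' Cohort feature table
#'
#' Stacks per-subject feature vectors into a numeric matrix (rows =
#' subjects) with a label vector, ready for [repeatedCV()].
#'
#' @param nets list of [DynamicNetwork-class] objects.
#' @param labels integer vector of binary labels, one per network.
#' @param aggregate,mode passed to [subjectFeatures()].
#' @return List with elements `features` (n x P matrix, rownames = subject
#'   ids) and `labels` (integer vector).
#' @export
cohortFeatures <- function(nets, labels, aggregate = c("mean", "concat"),
                           mode = c("onnela", "literal")) {
  aggregate <- match.arg(aggregate)
  mode <- match.arg(mode)
  stopifnot(length(nets) == length(labels))
  fvs <- lapply(seq_along(nets), function(i)
    subjectFeatures(nets[[i]], labels[i], aggregate, mode))
  features <- do.call(rbind, lapply(fvs, featureValues))
  rownames(features) <- vapply(fvs, subjectId, character(1))
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  list(features = features, labels = as.integer(labels))
}
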