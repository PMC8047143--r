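#' @include AllClasses.R
NULL

#' Number of sliding windows
#'
#' Number of overlapping windows a series of Q time points yields under a
#' given window width N and step S: K = floor((Q - N) / S) + 1. The floor
#' drops a trailing partial window when (Q - N) is not a multiple of S; for
#' step 1 this reduces to Q - N + 1.
#'
#' @param Q total number of time points.
#' @param spec a [WindowSpec-class].
#' @return Integer window count K >= 1.
#' @examples
#' countWindows(170, WindowSpec(50, 1))  # 121
#' @export
countWindows <- function(Q, spec) {
  stopifnot(is(spec, "WindowSpec"))
  Q <- as.integer(Q)
  if (spec@step < 1L)
    stop("invalid window spec: step must be positive", call. = FALSE)
  if (spec@width > Q)
    stop(sprintf(
      "invalid window spec: width %d exceeds series length %d",
      spec@width, Q), call. = FALSE)
  as.integer((Q - spec@width) %/% spec@step + 1L)
}

#' Standardize one windowed sub-series
#'
#' Centers every column to mean 0 and scales it to unit Euclidean norm, so
#' that the Gram matrix t(X) %*% X of the standardized window is exactly the
#' matrix of pairwise Pearson correlations (unit diagonal).
#'
#' @param window numeric matrix, window-width x P.
#' @return Matrix of the same shape with columns of mean 0 and norm 1.
#' @examples
#' w <- standardizeWindow(cbind(a = c(1, 2, 3), b = c(2, 1, 0)))
#' crossprod(w)  # Pearson correlations
#' @export
standardizeWindow <- function(window) {
  window <- as.matrix(window)
  centered <- sweep(window, 2L, colMeans(window), "-")
  norms <- sqrt(colSums(centered^2))
  bad <- which(norms == 0)
  if (length(bad))
    stop(sprintf(
      "degenerate signal: zero variance in region(s) %s within window",
      paste(bad, collapse = ", ")), call. = FALSE)
  sweep(centered, 2L, norms, "/")
}

# Start indices (1-based) of the K windows; window k covers
# start[k] .. start[k] + width - 1.
windowStarts <- function(Q, spec) {
  K <- countWindows(Q, spec)
  1L + (seq_len(K) - 1L) * spec@step
}

#' Sliding-window Pearson correlation networks
#'
#' Cuts the subject's series into K overlapping windows, standardizes each
#' window column-wise and forms the Pearson correlation matrix
#' t(X) %*% X per window — the conventional dynamic brain functional
#' network (DBFN).
#'
#' @param ts a [RoiTimeSeries-class].
#' @param spec a [WindowSpec-class].
#' @return A [DynamicNetwork-class] of K symmetric P x P matrices with unit
#'   diagonal and entries in \[-1, 1\].
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(240), 60, 4), "s01", 0L)
#' net <- pearsonDynamicNetwork(ts, WindowSpec(30, 10))
#' length(networkMatrices(net))  # 4
#' @export
pearsonDynamicNetwork <- function(ts, spec) {
  stopifnot(is(ts, "RoiTimeSeries"), is(spec, "WindowSpec"))
  X <- ts@data
  starts <- windowStarts(nrow(X), spec)
  mats <- lapply(seq_along(starts), function(k) {
    rows <- starts[k]:(starts[k] + spec@width - 1L)
    Xs <- tryCatch(standardizeWindow(X[rows, , drop = FALSE]),
                   error = function(e) stop(sprintf(
                     "window %d: %s", k, conditionMessage(e)),
                     call. = FALSE))
    W <- crossprod(Xs)
    W <- (W + t(W)) / 2           # exact symmetry against FP round-off
    diag(W) <- 1
    W
  })
  new("DynamicNetwork", matrices = mats, windowSpec = spec,
      subjectId = ts@subjectId)
}
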