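#' @include AllClasses.R
NULL

#' KNN hyper-edge incidence matrix
#'
#' Builds one hyper-edge per region: edge b contains its center vertex b
#' plus the k vertices nearest to b, so every edge degree is k + 1 and the
#' incidence matrix is P x P with a unit diagonal. Nearness is the
#' Euclidean distance between connectivity profiles (rows of W), with the
#' two self-entries (columns b and j) excluded from the comparison so that
#' the always-1 Pearson diagonal does not distort distances. Ties are
#' broken by lower vertex index.
#'
#' @param W symmetric P x P connectivity matrix.
#' @param k number of neighbors, 1 <= k <= P - 1.
#' @return Binary P x P incidence matrix (vertices x hyper-edges).
#' @examples
#' W <- matrix(0.2, 4, 4); diag(W) <- 1
#' knnHyperedges(W, 3)  # all-ones: every edge holds all vertices
#' @export
knnHyperedges <- function(W, k) {
  W <- as.matrix(W)
  P <- nrow(W)
  stopifnot(ncol(W) == P)
  k <- as.integer(k)
  if (k < 1L || k >= P)
    stop(sprintf("invalid k: need 1 <= k <= P - 1 = %d, got %d", P - 1L, k),
         call. = FALSE)
  H <- matrix(0, P, P)
  for (b in seq_len(P)) {
    d2 <- rep(Inf, P)
    for (j in seq_len(P)[-b]) {
      keep <- setdiff(seq_len(P), c(b, j))
      diff <- W[b, keep] - W[j, keep]
      d2[j] <- sum(diff * diff)
    }
    # order() with the index as secondary key: deterministic tie-break
    nn <- order(d2, seq_len(P))[seq_len(k)]
    H[c(b, nn), b] <- 1
  }
  H
}

#' Normalized hyper-graph Laplacian
#'
#' Given a binary incidence matrix H (vertices x hyper-edges) and positive
#' hyper-edge weights a, computes vertex degrees d(v) = sum_b a_b H(v, b),
#' edge degrees delta(b) = sum_v H(v, b), and the normalized Laplacian
#' L^h = I - D_v^{-1/2} H A D_e^{-1} H^T D_v^{-1/2}. L^h is symmetric PSD
#' and annihilates D_v^{1/2} 1 when the hyper-graph is connected.
#'
#' @param H binary incidence matrix.
#' @param a positive hyper-edge weights (default all 1).
#' @return Symmetric PSD matrix of size nrow(H).
#' @examples
#' H <- matrix(1, 4, 1)                   # one edge holding all vertices
#' hypergraphLaplacian(H)                 # I - J/4
#' @export
hypergraphLaplacian <- function(H, a = rep(1, ncol(H))) {
  H <- as.matrix(H)
  if (!all(H %in% c(0, 1)))
    stop("incidence matrix must be binary", call. = FALSE)
  a <- as.numeric(a)
  if (length(a) != ncol(H) || any(a <= 0))
    stop("need one positive weight per hyper-edge", call. = FALSE)
  d <- as.vector(H %*% a)
  if (any(d <= 0))
    stop(sprintf(
      "degenerate hyper-graph: isolated vertex (zero degree) at %s",
      paste(which(d <= 0), collapse = ", ")), call. = FALSE)
  delta <- colSums(H)
  Hs <- H / sqrt(d)                        # D_v^{-1/2} H
  Theta <- Hs %*% ((a / delta) * t(Hs))    # H A D_e^{-1} H^T, scaled
  L <- diag(nrow(H)) - Theta
  (L + t(L)) / 2
}

# Gaussian edge weights: a_b = exp(-m_b^2 / sigma^2) with m_b the mean
# distance from center b to its k neighbors and sigma the grand mean of the
# m_b (falls back to unit weights when all distances are zero).
gaussianEdgeWeights <- function(W, H) {
  P <- nrow(W)
  m <- vapply(seq_len(P), function(b) {
    nb <- setdiff(which(H[, b] == 1), b)
    db <- vapply(nb, function(j) {
      keep <- setdiff(seq_len(P), c(b, j))
      sqrt(sum((W[b, keep] - W[j, keep])^2))
    }, numeric(1))
    mean(db)
  }, numeric(1))
  sigma <- mean(m)
  if (sigma <= 0) return(rep(1, P))
  exp(-(m / sigma)^2)
}

#' Build a KNN hyper-graph from a connectivity matrix
#'
#' Convenience wrapper combining [knnHyperedges()], hyper-edge weighting
#' (unit weights by default; a Gaussian kernel on the mean center-to-
#' neighbor distance as an option) and [hypergraphLaplacian()] into a
#' [HyperGraph-class].
#'
#' @param W symmetric P x P connectivity matrix.
#' @param k number of neighbors.
#' @param edgeWeights "unit" or "gaussian".
#' @return A [HyperGraph-class].
#' @examples
#' W <- cor(matrix(rnorm(200), 20, 10))
#' hg <- buildHypergraph(W, k = 3)
#' range(eigen(laplacianMatrix(hg), symmetric = TRUE)$values)
#' @export
buildHypergraph <- function(W, k, edgeWeights = c("unit", "gaussian")) {
  edgeWeights <- match.arg(edgeWeights)
  H <- knnHyperedges(W, k)
  a <- switch(edgeWeights,
              unit = rep(1, ncol(H)),
              gaussian = gaussianEdgeWeights(as.matrix(W), H))
  new("HyperGraph", incidence = H, edgeWeights = a,
      vertexDegrees = as.vector(H %*% a), edgeDegrees = colSums(H),
      laplacian = hypergraphLaplacian(H, a))
}
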