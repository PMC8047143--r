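# Independent brute-force oracles used across the suite. These are written
# as plainly as possible (scalar loops, direct formula transcription) and
# never share code with the implementation they check.

randomSymmetric <- function(P, scale = 1) {
  M <- matrix(rnorm(P * P, sd = scale), P, P)
  (M + t(M)) / 2
}

randomCorrelationLike <- function(P, n = 4 * P) {
  stats::cor(matrix(rnorm(n * P), n, P))
}

# KNN hyper-edges by exhaustive pairwise distances, scalar arithmetic.
oracleKnnIncidence <- function(W, k) {
  P <- nrow(W)
  H <- matrix(0, P, P)
  for (b in seq_len(P)) {
    d <- rep(NA_real_, P)
    for (j in seq_len(P)) {
      if (j == b) next
      s <- 0
      for (c in seq_len(P)) {
        if (c == b || c == j) next
        s <- s + (W[b, c] - W[j, c])^2
      }
      d[j] <- sqrt(s)
    }
    ord <- order(d, seq_len(P), na.last = TRUE)
    H[b, b] <- 1
    for (nn in ord[seq_len(k)]) H[nn, b] <- 1
  }
  H
}

# Dense evaluation of the normalized hyper-graph Laplacian with explicit
# diagonal matrices.
oracleHypergraphLaplacian <- function(H, a) {
  Dv <- diag(as.vector(H %*% diag(a, nrow = length(a)) %*%
                         rep(1, ncol(H))), nrow = nrow(H))
  De <- diag(colSums(H), nrow = ncol(H))
  A <- diag(a, nrow = length(a))
  DvInvSqrt <- diag(1 / sqrt(diag(Dv)), nrow = nrow(H))
  Theta <- DvInvSqrt %*% H %*% A %*% solve(De) %*% t(H) %*% DvInvSqrt
  diag(nrow(H)) - Theta
}

# Onnela weighted clustering by triple loop over node triples.
oracleClustering <- function(W) {
  P <- nrow(W)
  A <- abs(W)
  diag(A) <- 0
  mx <- max(A)
  if (mx == 0) return(numeric(P))
  A <- A / mx
  C <- numeric(P)
  for (i in seq_len(P)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (jj in seq_along(nb)) for (hh in seq_along(nb)) {
      if (jj >= hh) next
      j <- nb[jj]; h <- nb[hh]
      s <- s + (A[i, j] * A[i, h] * A[j, h])^(1 / 3)
    }
    C[i] <- 2 * s / (k * (k - 1))
  }
  C
}

# Pairwise Pearson correlation of one window, textbook formula per pair.
oraclePearsonWindow <- function(X) {
  P <- ncol(X)
  M <- diag(P)
  for (i in seq_len(P)) for (j in seq_len(P)) {
    if (i == j) next
    xi <- X[, i] - mean(X[, i])
    xj <- X[, j] - mean(X[, j])
    M[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  M
}

# A tiny labelled cohort of pure-noise subjects.
noiseCohort <- function(n, P, Q, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    RoiTimeSeries(matrix(rnorm(Q * P), Q, P), sprintf("s%02d", i),
                  as.integer(i <= n / 2)))
}
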