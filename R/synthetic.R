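#' @include AllClasses.R
NULL

#' Group covariance matrix of a synthetic cohort
#'
#' Block-constant correlation matrix implied by a [CohortSpec-class]:
#' `rhoBetween` everywhere, `rhoWithin` inside each module, unit diagonal.
#' For the positive group, the within-module correlation of every affected
#' module is reduced by `effectDelta` (correlation attenuation). If the
#' implied matrix is not positive semi-definite it is shrunk toward the
#' identity by the minimal amount s, (1 - s) Sigma + s I, recorded in the
#' `"shrinkage"` attribute; s > 0.5 raises an error.
#'
#' @param spec a [CohortSpec-class].
#' @param positive TRUE for the positive (patient-like) group.
#' @return P x P covariance (= correlation) matrix with attribute
#'   `"shrinkage"`.
#' @examples
#' buildGroupCovariance(CohortSpec(P = 10, modules = list(1:5, 6:10)),
#'                      positive = TRUE)[1:5, 1:5]
#' @export
buildGroupCovariance <- function(spec, positive) {
  stopifnot(is(spec, "CohortSpec"))
  P <- spec@P
  Sigma <- matrix(spec@rhoBetween, P, P)
  for (m in seq_along(spec@modules)) {
    idx <- spec@modules[[m]]
    rho <- spec@rhoWithin
    if (positive && m %in% spec@affectedModules)
      rho <- rho - spec@effectDelta
    Sigma[idx, idx] <- rho
  }
  diag(Sigma) <- 1
  lmin <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  s <- 0
  if (lmin < 0) {
    s <- -lmin / (1 - lmin) + 1e-10
    if (s > 0.5)
      stop(sprintf(
        "invalid spec: correlations infeasible (required shrinkage %.3f > 0.5)",
        s), call. = FALSE)
    Sigma <- (1 - s) * Sigma + s * diag(P)
  }
  attr(Sigma, "shrinkage") <- s
  Sigma
}

# AR(1)-filter every column of E recursively: y_t = phi y_{t-1} + E_t.
arFilter <- function(E, phi) {
  if (phi == 0) return(E)
  out <- apply(E, 2L, function(col)
    as.numeric(stats::filter(col, phi, method = "recursive")))
  matrix(out, nrow = nrow(E))
}

#' Sample a synthetic two-group cohort of ROI time series
#'
#' For each subject, draws Q x P zero-mean Gaussian innovations with the
#' group covariance of [buildGroupCovariance()], passes each region's
#' series through a recursive AR(1) filter with coefficient `arCoeff`
#' (emulating the temporal autocorrelation of hemodynamic signals), and
#' adds white observation noise of sd `noiseSd`. Because the same filter
#' acts on every region, the AR step preserves the cross-region
#' correlation structure asymptotically; the white noise attenuates all
#' correlations uniformly.
#'
#' Every subject gets its own sub-seed drawn from the spec's master seed,
#' so the whole cohort is reproducible bit-for-bit and individual subjects
#' can be regenerated in isolation.
#'
#' @param spec a [CohortSpec-class].
#' @return List with `subjects` (list of [RoiTimeSeries-class], positives
#'   first) and `manifest` (data.frame with subject_id, label, seed, and
#'   the covariance shrinkage applied to each group).
#' @examples
#' cohort <- sampleCohort(CohortSpec(nPos = 3, nNeg = 3, seed = 42))
#' cohort$manifest
#' @export
sampleCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  sigmaPos <- buildGroupCovariance(spec, positive = TRUE)
  sigmaNeg <- buildGroupCovariance(spec, positive = FALSE)
  n <- spec@nPos + spec@nNeg
  set.seed(spec@seed)
  subSeeds <- sample.int(.Machine$integer.max, n)
  labels <- c(rep(1L, spec@nPos), rep(0L, spec@nNeg))
  ids <- c(sprintf("pos_%03d", seq_len(spec@nPos)),
           sprintf("neg_%03d", seq_len(spec@nNeg)))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subSeeds[i])
    Sigma <- if (labels[i] == 1L) sigmaPos else sigmaNeg
    E <- MASS::mvrnorm(spec@Q, mu = rep(0, spec@P), Sigma = Sigma)
    Y <- arFilter(E, spec@arCoeff)
    if (spec@noiseSd > 0)
      Y <- Y + matrix(stats::rnorm(spec@Q * spec@P, sd = spec@noiseSd),
                      spec@Q, spec@P)
    colnames(Y) <- sprintf("r%02d", seq_len(spec@P))
    subjects[[i]] <- RoiTimeSeries(Y, ids[i], labels[i])
  }
  manifest <- data.frame(
    subject_id = ids, label = labels, seed = subSeeds,
    shrinkage = ifelse(labels == 1L, attr(sigmaPos, "shrinkage"),
                       attr(sigmaNeg, "shrinkage")),
    stringsAsFactors = FALSE)
  list(subjects = subjects, manifest = manifest)
}
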