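#' @include AllClasses.R
NULL

#' Configuration for the ZINB batch-effect simulator
#'
#' Describes a synthetic study: batches of given sizes, OTUs with
#' log-uniform baseline abundances, two covariates (one standard
#' normal, one Bernoulli(0.5)), log-normal library sizes, a systematic
#' per-batch log-mean shift (gamma, auto-centered to the
#' sample-size-weighted sum-to-zero constraint), batch-specific
#' dispersions (nonsystematic distortion), and a logistic
#' structural-zero model with per-OTU intercepts, covariate effects
#' (zeta) and per-batch effects (psi).
#'
#' @param nPerBatch integer vector of batch sizes
#' @param m number of OTUs
#' @param batchNames batch labels (default "batch1", ...)
#' @param sigmaRange range of per-OTU log baseline abundance (relative
#'   scale; the library size enters as an offset)
#' @param beta length-2 covariate effects on log mean
#' @param gamma per-batch systematic log-mean shifts (length =
#'   number of batches; centered internally)
#' @param gammaOTUSd standard deviation of per-OTU jitter around
#'   \code{gamma} (each OTU draws its own batch shifts around the
#'   study-level ones and is re-centered; 0 gives every OTU the exact
#'   study-level shifts, useful for parameter-recovery checks)
#' @param theta per-batch NB dispersions (Var = mu + theta mu^2)
#' @param zeroIntercept range of per-OTU intercepts of the presence
#'   model (higher = fewer structural zeros)
#' @param zeta length-2 covariate effects on the presence logit
#' @param psi per-batch effects on the presence logit
#' @param libSizeLogMean,libSizeLogSd log-normal library size
#'   parameters
#' @param seed integer seed (mandatory)
#' @return a validated list of class \code{simConfig}
#' @export
simConfig <- function(nPerBatch, m, batchNames = NULL,
                      sigmaRange = c(-9, -4), beta = c(0.5, -0.5),
                      gamma = NULL, gammaOTUSd = 0, theta = NULL,
                      zeroIntercept = c(0.1, 2.1),
                      zeta = c(0.3, -0.3), psi = NULL,
                      libSizeLogMean = log(2e4), libSizeLogSd = 0.5,
                      seed = 1L) {
  k <- length(nPerBatch)
  if (k < 1 || any(nPerBatch < 1)) stop("nPerBatch must be positive")
  if (m < 1) stop("m must be positive")
  if (is.null(batchNames)) batchNames <- paste0("batch", seq_len(k))
  if (length(batchNames) != k) stop("batchNames length mismatch")
  if (is.null(gamma)) gamma <- rep(0, k)
  if (is.null(theta)) theta <- rep(0.5, k)
  if (is.null(psi)) psi <- rep(0, k)
  if (length(gamma) != k || length(theta) != k || length(psi) != k)
    stop("gamma, theta, psi must have one entry per batch")
  if (any(theta < 0)) stop("dispersions must be non-negative")
  if (length(beta) != 2 || length(zeta) != 2)
    stop("beta and zeta must have length 2 (one per covariate)")
  if (length(sigmaRange) != 2 || diff(sigmaRange) < 0)
    stop("sigmaRange must be an increasing range")
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory")
  if (gammaOTUSd < 0) stop("gammaOTUSd must be non-negative")
  w <- nPerBatch / sum(nPerBatch)
  gamma <- gamma - sum(w * gamma)  # weighted sum-to-zero
  structure(list(nPerBatch = as.integer(nPerBatch), m = as.integer(m),
                 batchNames = batchNames, sigmaRange = sigmaRange,
                 beta = beta, gamma = gamma, gammaOTUSd = gammaOTUSd,
                 theta = theta,
                 zeroIntercept = zeroIntercept, zeta = zeta, psi = psi,
                 libSizeLogMean = libSizeLogMean,
                 libSizeLogSd = libSizeLogSd, seed = as.integer(seed)),
            class = "simConfig")
}

#' Simulate a ZINB count table with known batch effects
#'
#' Draws library sizes log-normally, covariates (x1 ~ N(0,1),
#' x2 ~ Bernoulli(0.5)), per-OTU baselines sigma_j ~ U(sigmaRange) and
#' presence intercepts z0_j ~ U(zeroIntercept); then
#' log mu_ijg = sigma_j + X_i beta + gamma_g + log N_i,
#' Y ~ NB(mu, theta_g), and each count is structurally zeroed with
#' probability 1 - q_ij where
#' logit q_ij = z0_j + X_i zeta + psi_g. Fully reproducible given the
#' config seed.
#'
#' @param config a [simConfig()]
#' @return list with \code{counts} (OTU x sample integer matrix),
#'   \code{metadata} (data.frame: batch, x1, x2), and \code{truth}
#'   (per-OTU sigma, z0, the centered gamma, theta, beta, zeta, psi,
#'   target library sizes, and the structural-zero indicator matrix)
#' @seealso [simulateBatchExperiment()], [simPresets()]
#' @export
simulateCounts <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  k <- length(config$nPerBatch)
  n <- sum(config$nPerBatch)
  m <- config$m
  batch <- rep(config$batchNames, config$nPerBatch)
  N <- pmax(1, round(exp(stats::rnorm(n, config$libSizeLogMean,
                                      config$libSizeLogSd))))
  x1 <- stats::rnorm(n)
  x2 <- stats::rbinom(n, 1, 0.5)
  sigma <- stats::runif(m, config$sigmaRange[1], config$sigmaRange[2])
  z0 <- stats::runif(m, config$zeroIntercept[1], config$zeroIntercept[2])
  gIdx <- match(batch, config$batchNames)
  covEffect <- config$beta[1] * x1 + config$beta[2] * x2   # length n
  # per-OTU batch shifts around the study-level gamma, re-centered to
  # the sample-size-weighted sum-to-zero constraint per OTU
  w <- config$nPerBatch / n
  gammaOTU <- matrix(rep(config$gamma, each = m), m, k) +
    if (config$gammaOTUSd > 0)
      matrix(stats::rnorm(m * k, 0, config$gammaOTUSd), m, k)
    else 0
  gammaOTU <- gammaOTU - drop(gammaOTU %*% w)
  dimnames(gammaOTU) <- list(paste0("otu", seq_len(m)),
                             config$batchNames)
  logMu <- outer(sigma, covEffect + log(N), "+") + gammaOTU[, gIdx]
  mu <- exp(logMu)
  size <- 1 / pmax(config$theta[gIdx], 1e-8)
  Y <- matrix(stats::rnbinom(m * n, mu = mu,
                             size = rep(size, each = m)), m, n)
  etaQ <- outer(z0, config$zeta[1] * x1 + config$zeta[2] * x2 +
                  config$psi[gIdx], "+")
  q <- stats::plogis(etaQ)
  structZero <- matrix(stats::rbinom(m * n, 1, 1 - q), m, n)
  countsM <- Y * (1 - structZero)
  storage.mode(countsM) <- "integer"
  dimnames(countsM) <- list(paste0("otu", seq_len(m)),
                            paste0("sample", seq_len(n)))
  metadata <- data.frame(batch = batch, x1 = x1, x2 = x2,
                         row.names = colnames(countsM))
  truth <- list(sigma = sigma, z0 = z0, beta = config$beta,
                gamma = stats::setNames(config$gamma, config$batchNames),
                gammaOTU = gammaOTU,
                theta = stats::setNames(config$theta, config$batchNames),
                zeta = config$zeta,
                psi = stats::setNames(config$psi, config$batchNames),
                librarySizeTarget = N, q = q,
                structuralZero = structZero)
  list(counts = countsM, metadata = metadata, truth = truth)
}

#' Simulate directly into a BatchCountExperiment
#'
#' [simulateCounts()] followed by [BatchCountExperiment()], with
#' covariates x1 and x2 attached. Samples that come out all-zero (rare
#' under the defaults) are given a single pseudocount in their most
#' abundant OTU so the container's positive-library invariant holds.
#'
#' @param config a [simConfig()]
#' @return list with \code{experiment} and \code{truth}
#' @export
simulateBatchExperiment <- function(config) {
  sim <- simulateCounts(config)
  zeroLib <- colSums(sim$counts) == 0
  if (any(zeroLib)) {
    top <- which.max(rowSums(sim$counts))
    sim$counts[top, zeroLib] <- 1L
  }
  expt <- BatchCountExperiment(sim$counts, batch = sim$metadata$batch,
                               covariates = sim$metadata[, c("x1", "x2")],
                               minBatchSize = 1L)
  list(experiment = expt, truth = sim$truth)
}

#' Ready-made simulation presets
#'
#' Two presets emulating the batch structure of real multi-study
#' 16S data sets: \code{"hivrc_like"} (4 gut-microbiome batches of
#' sizes 232/43/23/62) and \code{"mouth_like"} (7 sequencing-plate
#' batches of sizes 43/49/56/79/89/88/91), each with 200 OTUs,
#' injected systematic shifts (gamma), batch-specific dispersions and
#' zero-rate distortions (theta, psi), and an overall zero fraction
#' near 31%.
#'
#' @param seed seed stored in each config (default 1)
#' @return named list of [simConfig()] objects
#' @export
simPresets <- function(seed = 1L) {
  list(
    hivrc_like = simConfig(
      nPerBatch = c(232L, 43L, 23L, 62L), m = 200L,
      gamma = c(0.8, -0.3, -0.6, 0.3), gammaOTUSd = 0.3,
      theta = c(0.3, 0.6, 0.45, 0.9),
      psi = c(0.5, -0.3, 0, -0.4),
      seed = seed),
    mouth_like = simConfig(
      nPerBatch = c(43L, 49L, 56L, 79L, 89L, 88L, 91L), m = 200L,
      gamma = c(0.6, -0.2, 0.3, -0.4, 0.1, -0.3, 0.2), gammaOTUSd = 0.3,
      theta = c(0.3, 0.5, 0.4, 0.7, 0.35, 0.6, 0.45),
      psi = c(0.3, -0.2, 0.1, -0.3, 0, 0.2, -0.1),
      seed = seed))
}
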