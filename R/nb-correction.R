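#' @include AllClasses.R
NULL

.THETA_FLOOR <- 1e-4
.THETA_CAP <- 1e4

#' Negative binomial variance
#'
#' Under the dispersion parameterisation used throughout the package,
#' Var(Y) = mu + theta * mu^2; theta -> 0 recovers the Poisson limit.
#'
#' @param mu mean, >= 0
#' @param theta dispersion, >= 0
#' @return mu + theta * mu^2
#' @export
nbVariance <- function(mu, theta) {
  if (any(mu < 0) || any(theta < 0))
    stop("mu and theta must be non-negative")
  mu + theta * mu^2
}

#' Fit the per-OTU negative binomial batch model
#'
#' Maximum-likelihood negative binomial regression of one OTU's
#' NON-ZERO counts on covariates and batch, with the log total library
#' size as a fixed offset:
#' log(mu) = sigma + X beta + gamma_g + log N.
#' The batch effects gamma_g are reported under the sample-size-weighted
#' sum-to-zero constraint (sum_g n_g gamma_g = 0 over the non-zero
#' observations), so the batch-free mean mu* = mu / exp(gamma_g) sits at
#' the weighted grand mean across batches. A single dispersion is
#' estimated jointly for the mean fit; per-batch dispersions theta_g are
#' then re-estimated by method of moments on the squared residuals
#' (solving Var = mu + theta mu^2 within each batch), floored at 1e-4
#' and capped at 1e4, and averaged arithmetically into theta*.
#'
#' @param y integer counts for one OTU (all samples; zeros are dropped
#'   internally)
#' @param X numeric covariate matrix (rows = samples; may have 0
#'   columns)
#' @param batch factor of batch labels per sample
#' @param offset log library sizes per sample
#' @return a list (class \code{nbFit}) with elements \code{sigma},
#'   \code{beta}, \code{gamma} (named per batch), \code{theta} (named
#'   per batch), \code{thetaStar}, \code{mu} and \code{muStar} (named by
#'   the non-zero samples), \code{converged}, \code{uncorrectable}
#' @export
fitNBOTU <- function(y, X, batch, offset) {
  batch <- factor(batch)
  nz <- which(y > 0)
  yv <- y[nz]
  bv <- factor(as.character(batch[nz]), levels = levels(batch))
  Xv <- X[nz, , drop = FALSE]
  off <- offset[nz]
  lv <- levels(batch)
  nB <- table(bv)

  bad <- function() list(sigma = NA_real_, beta = setNames(
    rep(NA_real_, ncol(X)), colnames(X)),
    gamma = setNames(rep(0, length(lv)), lv),
    theta = setNames(rep(NA_real_, length(lv)), lv),
    thetaStar = NA_real_, mu = NULL, muStar = NULL,
    converged = FALSE, uncorrectable = TRUE)

  # design: intercept + covariates + treatment-coded batch
  D <- cbind(`(Intercept)` = 1, Xv)
  if (length(lv) > 1) {
    Bd <- stats::model.matrix(~ bv)[, -1, drop = FALSE]
    colnames(Bd) <- lv[-1]
    D <- cbind(D, Bd)
  }
  if (qr(D)$rank < ncol(D)) return(bad())

  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(yv ~ D - 1 + offset(off))),
    error = function(e) NULL)
  converged <- !is.null(fit) && isTRUE(fit$converged)
  if (is.null(fit) || anyNA(stats::coef(fit))) {
    fit <- tryCatch(
      suppressWarnings(stats::glm(yv ~ D - 1 + offset(off),
                                  family = stats::poisson())),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(stats::coef(fit))) return(bad())
    converged <- FALSE
  }
  cf <- stats::coef(fit)
  names(cf) <- colnames(D)
  eff <- setNames(rep(0, length(lv)), lv)
  if (length(lv) > 1) eff[lv[-1]] <- cf[lv[-1]]
  wbar <- sum(as.numeric(nB) * eff) / sum(nB)
  gamma <- eff - wbar
  sigma <- unname(cf["(Intercept)"]) + wbar
  beta <- cf[colnames(Xv)]
  if (!ncol(Xv)) beta <- setNames(numeric(0), character(0))

  mu <- as.numeric(stats::fitted(fit))
  names(mu) <- names(y)[nz]
  muStar <- mu * exp(-gamma[as.character(bv)])
  names(muStar) <- names(mu)

  # per-batch method-of-moments dispersion: Var = mu + theta mu^2
  theta <- vapply(lv, function(g) {
    sel <- bv == g
    if (!sum(sel)) return(.THETA_FLOOR)
    num <- sum((yv[sel] - mu[sel])^2 - mu[sel])
    den <- sum(mu[sel]^2)
    th <- if (den > 0) num / den else .THETA_FLOOR
    min(max(th, .THETA_FLOOR), .THETA_CAP)
  }, numeric(1))
  if (!converged) theta[] <- .THETA_FLOOR
  thetaStar <- mean(theta)

  structure(list(sigma = sigma, beta = beta, gamma = gamma,
                 theta = theta, thetaStar = thetaStar,
                 mu = mu, muStar = muStar,
                 converged = converged, uncorrectable = FALSE),
            class = "nbFit")
}

# survival function of the zero-truncated NB: P(Y > q | Y > 0); working
# in the upper tail keeps deep-tail quantile levels at full precision
.truncSurv <- function(q, mu, theta) {
  size <- 1 / pmax(theta, .THETA_FLOOR / 100)
  f0 <- stats::pnbinom(0, mu = mu, size = size)
  ifelse(q < 1, 1,
         stats::pnbinom(q, mu = mu, size = size, lower.tail = FALSE) /
           pmax(1 - f0, .Machine$double.xmin))
}

#' Quantile-map a non-zero count between two negative binomials
#'
#' Transports an observed positive count from a source NB(muSrc,
#' thetaSrc) to a target NB(muTgt, thetaTgt), both truncated to the
#' positive support (the model is fitted on non-zero counts only). The
#' count's quantile level is the midpoint CDF level p = (F(y-1) +
#' F(y)) / 2 under the truncated source distribution; the mapped value
#' is the smallest positive integer whose truncated target CDF reaches
#' p. Deterministic and monotone in y.
#'
#' @param y positive integer count(s)
#' @param muSrc,thetaSrc source mean and dispersion (recycled over y)
#' @param muTgt,thetaTgt target mean and dispersion (recycled over y)
#' @return positive integer vector of mapped counts
#' @export
quantileMapCount <- function(y, muSrc, thetaSrc, muTgt, thetaTgt) {
  if (any(y < 1)) stop("quantileMapCount applies to positive counts only")
  if (any(c(muSrc, muTgt) <= 0) || any(c(thetaSrc, thetaTgt) < 0))
    stop("means must be positive and dispersions non-negative")
  n <- length(y)
  muSrc <- rep_len(muSrc, n); thetaSrc <- rep_len(thetaSrc, n)
  muTgt <- rep_len(muTgt, n); thetaTgt <- rep_len(thetaTgt, n)
  # midpoint level, expressed as an upper-tail probability so that far
  # tails do not collapse to 1 in double precision
  pUp <- (.truncSurv(y - 1, muSrc, thetaSrc) +
            .truncSurv(y, muSrc, thetaSrc)) / 2
  pUp <- pmin(pmax(pUp, .Machine$double.xmin), 1)
  sizeT <- 1 / pmax(thetaTgt, .THETA_FLOOR / 100)
  f0t <- stats::pnbinom(0, mu = muTgt, size = sizeT)
  # smallest y* >= 1 whose truncated upper tail drops to pUp
  pUpAbs <- pUp * pmax(1 - f0t, .Machine$double.xmin)
  out <- stats::qnbinom(pUpAbs, mu = muTgt, size = sizeT,
                        lower.tail = FALSE)
  pmax(out, 1)
}

#' Stage 1: remove systematic batch effects
#'
#' Fits [fitNBOTU()] to every correctable OTU and replaces each
#' non-zero count by its quantile-mapped value under the batch-free
#' distribution NB(mu*, theta*) (see [quantileMapCount()]). Zeros pass
#' through unchanged, as do OTUs flagged not correctable or whose
#' design is singular on the non-zero subset.
#'
#' @param object a \linkS4class{BatchCountExperiment}; run
#'   [filterOTUs()] first
#' @return list with \code{experiment} (the stage-1
#'   \linkS4class{BatchCountExperiment}) and \code{fits} (named list of
#'   per-OTU \code{nbFit} records for the correctable OTUs)
#' @export
correctSystematic <- function(object) {
  m <- counts(object)
  b <- batchLabels(object)
  X <- covariateMatrix(object)
  off <- log(librarySizes(object))
  keep <- correctableOTUs(object)
  out <- m
  fits <- vector("list", sum(keep))
  names(fits) <- rownames(m)[keep]
  singleBatch <- nlevels(b) == 1
  for (j in which(keep)) {
    y <- m[j, ]
    fit <- fitNBOTU(y, X, b, off)
    fits[[rownames(m)[j]]] <- fit
    if (fit$uncorrectable) next
    if (singleBatch) next  # gamma = 0 by constraint; identity map
    nz <- which(y > 0)
    gnz <- as.character(b[nz])
    mapped <- quantileMapCount(y[nz],
                               muSrc = fit$mu, thetaSrc = fit$theta[gnz],
                               muTgt = fit$muStar,
                               thetaTgt = fit$thetaStar)
    out[j, nz] <- as.integer(mapped)
  }
  expt <- object
  SummarizedExperiment::assay(expt, "counts") <- out
  methods::validObject(expt)
  list(experiment = expt, fits = fits)
}
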