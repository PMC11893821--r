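#' @include AllClasses.R
NULL

#' Quantile check loss
#'
#' rho_tau(u) = u * (tau - 1\{u < 0\}), the asymmetric absolute loss
#' whose minimiser over a location parameter is the tau-quantile.
#'
#' @param u residual(s)
#' @param tau quantile level in (0, 1)
#' @return non-negative loss, same length as \code{u}
#' @examples
#' checkLoss(4, 0.5)    # 2
#' checkLoss(-2, 0.25)  # 1.5
#' @export
checkLoss <- function(u, tau) {
  if (any(tau <= 0) || any(tau >= 1)) stop("tau must lie in (0, 1)")
  u * (tau - (u < 0))
}

#' Default quantile grid
#'
#' tau_s = s / (k + 1) for s = 1..k; with the default k = 19 this is
#' the 5th, 10th, ..., 95th percentiles.
#'
#' @param k number of grid points (default 19)
#' @return strictly increasing vector in (0, 1)
#' @export
tauGrid <- function(k = 19L) {
  k <- as.integer(k)
  stopifnot(k >= 1)
  seq_len(k) / (k + 1)
}

# objective of the composite problem at intercepts b (k) and slopes
# phi (p) given data y (n), S (n x p)
.cqrObjective <- function(y, S, taus, b, phi) {
  resid <- y - if (ncol(S)) drop(S %*% phi) else 0
  sum(vapply(seq_along(taus), function(s)
    sum(checkLoss(resid - b[s], taus[s])), numeric(1)))
}

# Composite quantile regression by smoothed iteratively reweighted
# least squares (Hunter-Lange MM surrogate of the check loss) with a
# decreasing smoothing schedule, plus an exact per-tau intercept reset
# each sweep (given slopes, the optimal intercepts are residual
# quantiles). Monotone-safeguarded on the true check-loss objective.
.cqrSolve <- function(y, S, taus, tol = 1e-7, maxit = 50L) {
  n <- length(y)
  k <- length(taus)
  p <- ncol(S)
  # stacked design: one block row per (observation, tau)
  Ik <- diag(k)
  Z <- cbind(Ik[rep(seq_len(k), each = n), , drop = FALSE],
             S[rep(seq_len(n), times = k), , drop = FALSE])
  yS <- rep(y, times = k)
  tv <- rep(taus - 0.5, each = n)
  phi <- if (p) rep(0, p) else numeric(0)
  b <- unname(stats::quantile(y, taus, type = 1))
  best <- list(b = b, phi = phi,
               obj = .cqrObjective(y, S, taus, b, phi))
  theta <- c(b, phi)
  for (eps in 10^seq(-1, -9, by = -1)) {
    for (it in seq_len(maxit)) {
      u <- yS - drop(Z %*% theta)
      cw <- 1 / (4 * (eps + abs(u)))
      A <- crossprod(Z, Z * (2 * cw))
      diag(A) <- diag(A) + 1e-10
      theta <- tryCatch(solve(A, crossprod(Z, 2 * cw * yS + tv)),
                        error = function(e) NULL)
      if (is.null(theta)) return(NULL)
      theta <- drop(theta)
      phiNew <- if (p) theta[k + seq_len(p)] else numeric(0)
      # exact intercepts given the new slopes
      resid <- y - if (p) drop(S %*% phiNew) else 0
      bNew <- unname(stats::quantile(resid, taus, type = 1))
      objNew <- .cqrObjective(y, S, taus, bNew, phiNew)
      theta <- c(bNew, phiNew)
      improved <- objNew < best$obj - tol * max(1, best$obj)
      if (objNew < best$obj) best <- list(b = bNew, phi = phiNew,
                                          obj = objNew)
      if (!improved) break
    }
  }
  best
}

#' Fit the per-OTU composite quantile regression
#'
#' Models the conditional quantiles of an OTU's non-zero adjusted
#' counts as Q(tau | X, batch) = b(tau) + X' alpha + B' delta over the
#' grid \code{taus}. In \code{"composite"} mode (the default) the
#' covariate and batch coefficients are shared across all quantile
#' levels and only the intercepts vary with tau -- the objective is the
#' summed check loss over the whole grid. In \code{"per_tau"} mode each
#' grid level is fitted independently with its own coefficients. Batch
#' is reference-coded against \code{refLevel} (delta = 0 there).
#' Fitted grid predictions are monotone-rearranged (sorted) at
#' prediction time, so quantile crossing cannot propagate.
#'
#' With fewer observations than (covariates + batches + grid size), or
#' on solver failure, the fit falls back to per-batch empirical
#' quantiles and is flagged (\code{method = "empirical"}).
#'
#' @param y positive (non-zero) adjusted counts
#' @param X numeric covariate matrix (rows match \code{y})
#' @param batch factor of batch labels (rows match \code{y})
#' @param taus quantile grid, default [tauGrid()] with k = 19
#' @param mode \code{"composite"} or \code{"per_tau"}
#' @param refLevel batch level coded as reference (default: first
#'   level of \code{batch})
#' @return list (class \code{cqrFit}); key elements: \code{method},
#'   \code{taus}, \code{intercepts}, \code{alpha}, \code{delta} (per
#'   batch, reference 0) for composite mode; matrices
#'   \code{interceptsMat}/\code{alphaMat}/\code{deltaMat} for per-tau
#'   mode; \code{gridByBatch} for the empirical fallback;
#'   \code{minPositive}; \code{objective}
#' @export
fitCQROTU <- function(y, X, batch, taus = tauGrid(),
                      mode = c("composite", "per_tau"),
                      refLevel = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(y > 0), all(diff(taus) > 0), all(taus > 0 & taus < 1))
  batch <- factor(batch)
  lv <- levels(batch)
  if (is.null(refLevel)) refLevel <- lv[1]
  stopifnot(refLevel %in% lv)
  ord <- c(refLevel, setdiff(lv, refLevel))
  bRef <- factor(as.character(batch), levels = ord)
  covNames <- colnames(X)
  Bd <- if (length(lv) > 1) {
    md <- stats::model.matrix(~ bRef)[, -1, drop = FALSE]
    colnames(md) <- ord[-1]
    md
  } else matrix(numeric(0), nrow = length(y), ncol = 0)
  S <- cbind(X, Bd)
  k <- length(taus)
  base <- list(taus = taus, covNames = covNames, batchLevels = lv,
               refLevel = refLevel, minPositive = min(y))

  empirical <- function() {
    grid <- vapply(lv, function(g) {
      yg <- y[batch == g]
      if (!length(yg)) yg <- y
      unname(stats::quantile(yg, taus, type = 1))
    }, numeric(k))
    if (k == 1) grid <- matrix(grid, nrow = 1, dimnames = list(NULL, lv))
    obj <- sum(vapply(seq_len(k), function(s)
      sum(checkLoss(y - grid[s, as.character(batch)], taus[s])),
      numeric(1)))
    structure(c(base, list(method = "empirical", gridByBatch = grid,
                           objective = obj, fallback = TRUE)),
              class = "cqrFit")
  }

  if (length(y) < ncol(S) + length(lv) + k ||
      (ncol(S) > 0 && qr(S)$rank < ncol(S)))
    return(empirical())

  if (mode == "composite") {
    sol <- .cqrSolve(y, S, taus)
    if (is.null(sol)) return(empirical())
    alpha <- if (length(covNames))
      setNames(sol$phi[seq_along(covNames)], covNames)
      else setNames(numeric(0), character(0))
    delta <- setNames(rep(0, length(lv)), lv)
    if (length(lv) > 1)
      delta[ord[-1]] <- sol$phi[length(covNames) + seq_len(length(lv) - 1)]
    structure(c(base, list(method = "composite",
                           intercepts = sol$b, alpha = alpha,
                           delta = delta, objective = sol$obj,
                           fallback = FALSE)),
              class = "cqrFit")
  } else {
    p <- ncol(S)
    interceptsMat <- numeric(k)
    alphaMat <- matrix(0, k, length(covNames),
                       dimnames = list(NULL, covNames))
    deltaMat <- matrix(0, k, length(lv), dimnames = list(NULL, lv))
    objective <- 0
    for (s in seq_len(k)) {
      sol <- .cqrSolve(y, S, taus[s])
      if (is.null(sol)) return(empirical())
      interceptsMat[s] <- sol$b
      if (length(covNames)) alphaMat[s, ] <- sol$phi[seq_along(covNames)]
      if (length(lv) > 1)
        deltaMat[s, ord[-1]] <-
          sol$phi[length(covNames) + seq_len(length(lv) - 1)]
      objective <- objective + sol$obj
    }
    structure(c(base, list(method = "per_tau",
                           interceptsMat = interceptsMat,
                           alphaMat = alphaMat, deltaMat = deltaMat,
                           objective = objective, fallback = FALSE)),
              class = "cqrFit")
  }
}

# raw (pre-rearrangement) grid predictions for one sample
.cqrGridValues <- function(fit, XRow, batch) {
  batch <- as.character(batch)
  xr <- if (is.null(names(XRow)) || !length(XRow)) as.numeric(XRow)
        else as.numeric(XRow[fit$covNames])
  switch(fit$method,
    composite = fit$intercepts +
      (if (length(xr)) sum(xr * fit$alpha) else 0) +
      unname(fit$delta[batch]),
    per_tau = fit$interceptsMat +
      (if (length(xr)) drop(fit$alphaMat %*% xr) else 0) +
      fit$deltaMat[, batch],
    empirical = fit$gridByBatch[, batch])
}

#' Predict a conditional quantile
#'
#' Evaluates the fitted quantile function for one sample and an
#' arbitrary batch context. Grid predictions are monotone-rearranged
#' (sorted in tau), floored at the smallest observed positive count of
#' the OTU, interpolated piecewise-linearly between grid levels, and
#' extrapolated as constants beyond the grid.
#'
#' @param fit a \code{cqrFit} from [fitCQROTU()]
#' @param XRow numeric covariate vector for a sample
#' @param batch a single batch label (e.g. the reference batch, for a
#'   counterfactual prediction)
#' @param tau quantile level(s) in (0, 1)
#' @return predicted value(s), never below the positive floor
#' @export
predictQuantile <- function(fit, XRow, batch, tau) {
  if (any(tau <= 0) || any(tau >= 1)) stop("tau must lie in (0, 1)")
  v <- pmax(sort(.cqrGridValues(fit, XRow, batch)), fit$minPositive)
  if (length(v) == 1) return(rep(v, length(tau)))
  stats::approx(fit$taus, v, xout = tau, rule = 2)$y
}

#' Build a zero-inflated quantile function
#'
#' Combines a non-zero probability q with a positive-part quantile
#' function into the two-branch composite quantile function
#' Qc(tau) = 0 for tau < 1 - q, and Qc(tau) = Q((tau - (1 - q)) / q)
#' otherwise, where Q interpolates the positive grid values.
#'
#' @param q non-zero probability for the (sample, batch) context
#' @param values positive-branch grid values (rearranged and floored
#'   as in [predictQuantile()])
#' @param taus the quantile grid the values sit on
#' @return list (class \code{ziqf}) with elements \code{q},
#'   \code{values}, \code{taus}
#' @export
ziQuantileFunction <- function(q, values, taus) {
  stopifnot(q > 0, q < 1, length(values) == length(taus))
  structure(list(q = q, values = sort(values), taus = taus),
            class = "ziqf")
}

.positiveQF <- function(values, taus, tauPrime) {
  if (length(values) == 1) return(rep(values, length(tauPrime)))
  stats::approx(taus, values, xout = pmin(pmax(tauPrime, taus[1]),
                                          taus[length(taus)]))$y
}

#' Evaluate a zero-inflated quantile function
#'
#' @param qf a \code{ziqf} from [ziQuantileFunction()]
#' @param tau level(s) in (0, 1)
#' @return 0 on the zero branch, otherwise the rescaled positive
#'   quantile
#' @export
ziQuantile <- function(qf, tau) {
  stopifnot(all(tau > 0), all(tau < 1))
  out <- numeric(length(tau))
  pos <- tau >= 1 - qf$q
  if (any(pos)) {
    tp <- (tau[pos] - (1 - qf$q)) / qf$q
    out[pos] <- .positiveQF(qf$values, qf$taus, tp)
  }
  out
}

# transport one stage-1 value from its own context onto the reference
# context. In-range positive values travel via their quantile level;
# values outside the positive grid travel additively from the
# transported grid edge, which keeps the map monotone in y and an
# exact identity when both contexts coincide.
.transportValue <- function(y, vOwn, vRef, qOwn, qRef, taus,
                            tauZero = NULL) {
  k <- length(vOwn)
  inRange <- function(yy) {
    tauP <- .positiveLevel(vOwn, taus, yy)
    tauObs <- (1 - qOwn) + qOwn * tauP
    if (tauObs < 1 - qRef) 0
    else .positiveQF(vRef, taus, (tauObs - (1 - qRef)) / qRef)
  }
  if (y == 0) {
    tauObs <- if (is.null(tauZero)) (1 - qOwn) / 2 else tauZero
    tauObs <- min(max(tauObs, 1e-9), 1 - 1e-9)
    if (tauObs < 1 - qRef) return(0)
    return(.positiveQF(vRef, taus, (tauObs - (1 - qRef)) / qRef))
  }
  if (y > vOwn[k]) return(inRange(vOwn[k]) + (y - vOwn[k]))
  if (y < vOwn[1]) return(max(0, inRange(vOwn[1]) - (vOwn[1] - y)))
  inRange(y)
}

# midpoint of the preimage interval of y under the piecewise-linear
# positive branch (constant extrapolation beyond the grid); exact for
# piecewise-linear functions, no numeric root finding needed
.positiveLevel <- function(values, taus, y) {
  v <- values
  k <- length(v)
  if (y < v[1]) return(taus[1])          # below the floor: clamp
  if (y > v[k]) return(taus[k])          # above the grid: clamp
  i1 <- which(v >= y)[1]
  if (v[i1] > y) {                        # strictly between two knots
    return(taus[i1 - 1] + (y - v[i1 - 1]) / (v[i1] - v[i1 - 1]) *
             (taus[i1] - taus[i1 - 1]))
  }
  i2 <- max(which(v <= y))                # v[i1] == y == v[i2]
  a <- if (i1 == 1) 0 else taus[i1]
  b <- if (i2 == k) 1 else taus[i2]
  (a + b) / 2
}

#' Quantile level of an observed value under a zero-inflated quantile
#' function
#'
#' The inverse of [ziQuantile()], used to transport a sample onto the
#' reference batch: an observed zero is assigned the midpoint of the
#' zero mass, tau = (1 - q) / 2; a positive value y is assigned
#' tau = (1 - q) + q * tau', where tau' is the midpoint of the
#' preimage interval of y under the positive branch. Values below the
#' positive branch's minimum clamp tau' to the first grid level.
#'
#' @param qf a \code{ziqf} from [ziQuantileFunction()]
#' @param y observed value, >= 0
#' @return level in (0, 1)
#' @export
ziQuantileLevel <- function(qf, y) {
  stopifnot(y >= 0)
  if (y == 0) return((1 - qf$q) / 2)
  (1 - qf$q) + qf$q * .positiveLevel(qf$values, qf$taus, y)
}

#' Stage 2: remove nonsystematic batch effects
#'
#' Transports every sample of every correctable OTU onto the reference
#' batch. For sample i in batch g and OTU j, the observed stage-1 value
#' is converted to a quantile level under the sample's own-context
#' zero-inflated quantile function (presence probability and quantiles
#' predicted with the sample's own batch) and re-materialised under the
#' reference-context function (same covariates, batch indicators set to
#' the reference batch). Results are rounded half-to-even to
#' non-negative integers. Samples already in the reference batch, and
#' OTUs without usable fits, pass through unchanged.
#'
#' @param stage1 the stage-1 \linkS4class{BatchCountExperiment}
#' @param zeroFits named list of \code{zeroFit} records (one per
#'   correctable OTU), as from [fitZeroOTU()]
#' @param cqrFits named list of \code{cqrFit} records, as from
#'   [fitCQROTU()]
#' @param reference the reference batch label
#' @param stochasticZeros if TRUE, observed zeros draw their level
#'   uniformly from the zero mass (0, 1 - q) instead of its midpoint;
#'   requires a seed set by the caller
#' @return a \linkS4class{BatchCountExperiment} of corrected counts
#' @export
correctNonsystematic <- function(stage1, zeroFits, cqrFits, reference,
                                 stochasticZeros = FALSE) {
  m <- counts(stage1)
  b <- as.character(batchLabels(stage1))
  X <- covariateMatrix(stage1)
  stopifnot(reference %in% b)
  out <- m
  nonRef <- which(b != reference)
  for (otu in names(cqrFits)) {
    zf <- zeroFits[[otu]]
    cf <- cqrFits[[otu]]
    if (is.null(zf) || is.null(cf)) next
    j <- match(otu, rownames(m))
    # vectorised presence probabilities in both contexts
    qOwn <- zf$q
    if (zf$degenerate) {
      qRef <- rep(unname(zf$q[1]), ncol(m))
    } else {
      etaRef <- unname(zf$coef["(Intercept)"]) +
        (if (length(zf$zeta)) drop(X[, zf$covNames, drop = FALSE] %*%
                                     zf$zeta) else 0) +
        unname(zf$psi[reference])
      qRef <- rep_len(pmin(pmax(stats::plogis(etaRef), .Q_CLAMP),
                           1 - .Q_CLAMP), ncol(m))
    }
    for (i in nonRef) {
      y <- m[j, i]
      vOwn <- pmax(sort(.cqrGridValues(cf, X[i, ], b[i])), cf$minPositive)
      vRef <- pmax(sort(.cqrGridValues(cf, X[i, ], reference)),
                   cf$minPositive)
      qO <- unname(qOwn[i]); qR <- unname(qRef[i])
      tauZero <- if (y == 0 && stochasticZeros)
        stats::runif(1, 0, 1 - qO) else NULL
      z <- .transportValue(y, vOwn, vRef, qO, qR, cf$taus, tauZero)
      out[j, i] <- max(0, round(z))
    }
  }
  expt <- stage1
  storage.mode(out) <- "integer"
  SummarizedExperiment::assay(expt, "counts") <- out
  expt
}
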