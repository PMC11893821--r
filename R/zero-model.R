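#' @include AllClasses.R
NULL

.Q_CLAMP <- 1e-6

# Ridge-penalised logistic regression by Newton iteration.
# The quadratic penalty (lambda on every non-intercept coefficient)
# keeps quasi-separated fits finite, which is routine for sparse OTUs.
.ridgeLogistic <- function(Z, yBin, lambda = 1e-4, maxit = 100L,
                           tol = 1e-10) {
  p <- ncol(Z)
  pen <- rep(lambda, p)
  pen[colnames(Z) == "(Intercept)"] <- 0
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Z, yBin - mu)) - pen * beta
    H <- crossprod(Z * w, Z)
    diag(H) <- diag(H) + pen + 1e-12
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  names(beta) <- colnames(Z)
  beta
}

#' Fit the per-OTU presence (zero) model
#'
#' Logistic regression of the presence indicator 1\{y* > 0\} on
#' covariates and batch:
#' logit Pr(Y* > 0) = intercept + X' zeta + B' psi,
#' giving each sample's non-zero probability q_ij. Batch enters as a
#' fixed effect, reference-coded against \code{refLevel}. A small ridge
#' penalty (lambda = 1e-4 on non-intercept terms) guards against
#' separation. Degenerate OTUs are handled without fitting: all
#' non-zero gives q = 1 - 1e-6 (flagged), all zero gives q = 1e-6.
#'
#' @param yStar adjusted counts for one OTU (all samples)
#' @param X numeric covariate matrix (rows = samples)
#' @param batch factor of batch labels
#' @param refLevel batch level used as the coding reference (default:
#'   first level)
#' @return list (class \code{zeroFit}) with \code{coef} (named:
#'   intercept, covariates, batch dummies), \code{zeta}, \code{psi}
#'   (batch effects on the linear predictor, reference level 0),
#'   \code{q} (per-sample probabilities, clamped to
#'   [1e-6, 1 - 1e-6]), \code{separation} flag, plus the coding
#'   metadata needed by [predictQ()]
#' @export
fitZeroOTU <- function(yStar, X, batch, refLevel = NULL) {
  batch <- factor(batch)
  if (is.null(refLevel)) refLevel <- levels(batch)[1]
  stopifnot(refLevel %in% levels(batch))
  lv <- levels(batch)
  yBin <- as.numeric(yStar > 0)
  covNames <- colnames(X)
  base <- list(covNames = covNames, batchLevels = lv, refLevel = refLevel)
  if (all(yBin == 1) || all(yBin == 0)) {
    qv <- rep(if (all(yBin == 1)) 1 - .Q_CLAMP else .Q_CLAMP,
              length(yStar))
    names(qv) <- names(yStar)
    return(structure(c(base, list(
      coef = setNames(rep(0, 1 + length(covNames) + length(lv) - 1),
                      c("(Intercept)", covNames, setdiff(lv, refLevel))),
      zeta = setNames(rep(0, length(covNames)), covNames),
      psi = setNames(rep(0, length(lv)), lv),
      q = qv, degenerate = TRUE, separation = TRUE)),
      class = "zeroFit"))
  }
  ord <- c(refLevel, setdiff(lv, refLevel))
  bRef <- factor(as.character(batch), levels = ord)
  Z <- cbind(`(Intercept)` = 1, X)
  if (length(lv) > 1) {
    Bd <- stats::model.matrix(~ bRef)[, -1, drop = FALSE]
    colnames(Bd) <- ord[-1]
    # drop collinear batch columns (e.g. a batch absent from the data)
    ok <- qr(cbind(Z, Bd))$rank == ncol(Z) + ncol(Bd)
    if (!ok) {
      keep <- logical(ncol(Bd))
      for (c0 in seq_len(ncol(Bd))) {
        cand <- cbind(Z, Bd[, which(keep), drop = FALSE], Bd[, c0])
        keep[c0] <- qr(cand)$rank == ncol(cand)
      }
      Bd <- Bd[, keep, drop = FALSE]
    }
    Z <- cbind(Z, Bd)
  }
  cf <- .ridgeLogistic(Z, yBin)
  psi <- setNames(rep(0, length(lv)), lv)
  extra <- intersect(names(cf), lv)
  psi[extra] <- cf[extra]
  qv <- pmin(pmax(stats::plogis(drop(Z %*% cf)), .Q_CLAMP), 1 - .Q_CLAMP)
  names(qv) <- names(yStar)
  sep <- max(abs(cf)) > 15
  structure(c(base, list(
    coef = cf,
    zeta = if (length(covNames)) cf[covNames]
           else setNames(numeric(0), character(0)),
    psi = psi, q = qv, degenerate = FALSE, separation = sep)),
    class = "zeroFit")
}

#' Predict a non-zero probability, possibly counterfactually
#'
#' Evaluates the fitted presence model for one sample's covariates and
#' an arbitrary batch context -- in particular the reference batch,
#' which is how the correction step asks "how likely would this sample
#' be non-zero had it been processed in the reference batch".
#'
#' @param fit a \code{zeroFit} from [fitZeroOTU()]
#' @param XRow numeric covariate vector for a sample (names must match
#'   the fit)
#' @param batch a single batch label
#' @return probability in [1e-6, 1 - 1e-6]
#' @export
predictQ <- function(fit, XRow, batch) {
  batch <- as.character(batch)
  if (!batch %in% fit$batchLevels)
    stop("unknown batch label '", batch, "'")
  if (length(XRow) != length(fit$covNames))
    stop("covariate vector length does not match the fit")
  if (fit$degenerate) return(unname(fit$q[1]))
  xv <- if (is.null(names(XRow)) || !length(XRow)) XRow
        else XRow[fit$covNames]
  eta <- unname(fit$coef["(Intercept)"]) +
    (if (length(xv)) sum(xv * fit$zeta) else 0) +
    unname(fit$psi[batch])
  min(max(stats::plogis(eta), .Q_CLAMP), 1 - .Q_CLAMP)
}
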