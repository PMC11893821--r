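# small in-code fixtures shared across test files

# deterministic toy experiment: 2 batches, Poisson-ish counts, one
# numeric and one categorical covariate
makeToyExperiment <- function(n = 20, m = 8, seed = 42, gamma = 0,
                              theta = c(0.3, 0.3), psi = c(0, 0)) {
  cfg <- simConfig(nPerBatch = c(n, n), m = m,
                   gamma = c(gamma, -gamma), theta = theta, psi = psi,
                   seed = seed)
  simulateBatchExperiment(cfg)$experiment
}

# brute-force tie-corrected Kruskal-Wallis H, straight from the rank
# definition (independent of stats::kruskal.test)
bruteKW <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  n <- length(x)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# pmf-enumeration oracle for the truncated-NB quantile map. Works with
# tail sums accumulated from the far end (a sum of positives keeps
# full relative precision deep in the tail, where a forward cumsum of
# the cdf saturates at 1).
bruteQuantileMap <- function(y, muSrc, thetaSrc, muTgt, thetaTgt,
                             maxY = 500000L) {
  upto <- max(y * 4, 500)
  # enumerate until the un-summed tail is negligible relative to every
  # survival level the comparison can touch
  while (pnbinom(upto, mu = max(muSrc, muTgt),
                 size = 1 / max(thetaSrc, thetaTgt),
                 lower.tail = FALSE) > 1e-300 && upto < maxY)
    upto <- upto * 2
  tailFrom <- function(mu, theta) {
    pm <- dnbinom(seq_len(upto), mu = mu, size = 1 / theta)
    rev(cumsum(rev(pm)))  # tailFrom[t] = P(t <= Y <= upto)
  }
  tS <- tailFrom(muSrc, thetaSrc)
  tT <- tailFrom(muTgt, thetaTgt)
  p0S <- dnbinom(0, mu = muSrc, size = 1 / thetaSrc)
  p0T <- dnbinom(0, mu = muTgt, size = 1 / thetaTgt)
  # midpoint level as an upper-tail probability of the truncated source
  pUp <- (tS[y] + c(tS, 0)[y + 1]) / 2 / (1 - p0S)
  vapply(pUp, function(pp) {
    idx <- which(c(tT, 0)[-1] / (1 - p0T) <= pp)[1]
    if (is.na(idx)) upto else idx
  }, numeric(1))
}

# total check-loss objective of a composite quantile fit evaluated at
# arbitrary intercepts/slopes (independent of the package optimiser)
bruteCQRObjective <- function(y, S, taus, b, phi) {
  resid <- y - if (length(phi)) drop(S %*% phi) else 0
  sum(vapply(seq_along(taus),
             function(s) sum(checkLoss(resid - b[s], taus[s])),
             numeric(1)))
}
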