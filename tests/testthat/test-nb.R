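test_that("negative binomial variance follows mu + theta mu^2", {
  expect_equal(nbVariance(10, 0.5), 60)
  expect_equal(nbVariance(7, 0), 7)           # Poisson limit
  expect_equal(nbVariance(0, 3), 0)
  expect_error(nbVariance(-1, 0.5), "non-negative")
  expect_error(nbVariance(1, -0.5), "non-negative")
})

test_that("NB fit recovers batch effects and satisfies the constraint identities", {
  set.seed(101)
  n <- 500
  batch <- factor(rep(c("g1", "g2"), each = n))
  X <- cbind(x1 = rnorm(2 * n))
  offset <- rep(log(1e4), 2 * n)
  gammaTrue <- c(g1 = 0.8, g2 = -0.8)
  thetaTrue <- c(g1 = 0.3, g2 = 0.6)
  for (rep in 1:5) {
    sigma <- runif(1, -6, -5)
    mu <- exp(sigma + 0.5 * X[, 1] + gammaTrue[batch] + offset)
    y <- rnbinom(2 * n, mu = mu, size = 1 / thetaTrue[batch])
    names(y) <- paste0("s", seq_along(y))
    fit <- fitNBOTU(y, X, batch, offset)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$gamma - gammaTrue)), 0.1)
    # weighted sum-to-zero over the non-zero observations
    nB <- table(batch[y > 0])
    expect_equal(sum(as.numeric(nB) * fit$gamma), 0, tolerance = 1e-8)
    # adjusted mean identity: log mu* = log mu - gamma, exactly
    g <- as.character(batch[y > 0])
    expect_equal(log(fit$muStar), log(fit$mu) - fit$gamma[g],
                 ignore_attr = TRUE, tolerance = 1e-12)
    # pooled dispersion is the arithmetic mean of the per-batch ones
    expect_equal(fit$thetaStar, mean(fit$theta))
  }
})

test_that("single-batch fits carry zero batch effect and identity means", {
  set.seed(5)
  y <- rnbinom(200, mu = 50, size = 2)
  names(y) <- paste0("s", 1:200)
  fit <- fitNBOTU(y, matrix(numeric(0), 200, 0), factor(rep("only", 200)),
                  rep(log(1e4), 200))
  expect_equal(unname(fit$gamma), 0)
  expect_equal(fit$mu, fit$muStar)
})

test_that("quantile map is the identity when source equals target", {
  for (pars in list(c(5, 0.3), c(50, 0.01), c(2, 2))) {
    y <- 1:60
    expect_identical(
      as.integer(quantileMapCount(y, pars[1], pars[2], pars[1], pars[2])),
      y)
  }
})

test_that("quantile map agrees with the pmf-enumeration oracle", {
  set.seed(9)
  for (rep in 1:10) {
    muS <- runif(1, 2, 80); muT <- runif(1, 2, 80)
    thS <- runif(1, 0.01, 1.5); thT <- runif(1, 0.01, 1.5)
    y <- 1:120
    expect_identical(unname(quantileMapCount(y, muS, thS, muT, thT)),
                     unname(bruteQuantileMap(y, muS, thS, muT, thT)))
  }
})

test_that("quantile map is monotone in the observed count", {
  set.seed(21)
  for (rep in 1:10) {
    muS <- runif(1, 1, 50); muT <- runif(1, 1, 50)
    thS <- runif(1, 0.01, 2); thT <- runif(1, 0.01, 2)
    mapped <- quantileMapCount(1:200, muS, thS, muT, thT)
    expect_true(all(diff(mapped) >= 0))
  }
})

test_that("stage 1 leaves zeros and single-batch tables untouched", {
  expt <- makeToyExperiment(n = 15, m = 6, seed = 77, gamma = 0.6)
  expt <- filterOTUs(expt, 0.1, 3)
  st1 <- correctSystematic(expt)
  expect_identical(counts(st1$experiment) == 0L, counts(expt) == 0L)

  cfg <- simConfig(nPerBatch = 30, m = 6, seed = 3)
  single <- simulateBatchExperiment(cfg)$experiment
  single <- filterOTUs(single, 0, 0)
  st <- correctSystematic(single)
  expect_identical(counts(st$experiment), counts(single))
})

test_that("batch-effect recovery error shrinks as samples accumulate", {
  # fit against the generative library offsets from the truth record:
  # with realised totals as offset, a batch shift common to all OTUs
  # is absorbed into the library size and only composition-level
  # effects are identifiable (stage 2 handles the scale component)
  mae <- vapply(c(50, 200, 800), function(n) {
    cfg <- simConfig(nPerBatch = c(n, n), m = 25, sigmaRange = c(-6, -4),
                     gamma = c(0.8, -0.8), gammaOTUSd = 0.4,
                     theta = c(0.3, 0.6), zeroIntercept = c(4, 5),
                     seed = 1234)
    sim <- simulateCounts(cfg)
    X <- as.matrix(sim$metadata[, c("x1", "x2")])
    batch <- factor(sim$metadata$batch)
    off <- log(sim$truth$librarySizeTarget)
    errs <- vapply(rownames(sim$counts), function(otu) {
      f <- fitNBOTU(sim$counts[otu, ], X, batch, off)
      if (f$uncorrectable) return(NA_real_)
      mean(abs(f$gamma - sim$truth$gammaOTU[otu, ]))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})
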