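test_that("check loss matches its definition", {
  expect_equal(checkLoss(0, 0.3), 0)
  expect_equal(checkLoss(4, 0.5), 2)
  expect_equal(checkLoss(-2, 0.25), 1.5)
  set.seed(2)
  u <- rnorm(50); tau <- 0.7
  expect_true(all(checkLoss(u, tau) >= 0))
  expect_error(checkLoss(1, 1), "tau")
  expect_error(checkLoss(1, 0), "tau")
})

test_that("intercept-only fits recover empirical quantiles", {
  set.seed(17)
  y <- rpois(80, 20) + 1
  X0 <- matrix(numeric(0), 80, 0)
  b <- factor(rep("one", 80))

  # single tau = 0.5: attained loss equals the brute-force minimum over
  # candidate locations (an order statistic always minimises check loss)
  fit1 <- fitCQROTU(y, X0, b, taus = 0.5)
  bruteBest <- min(vapply(sort(unique(y)),
                          function(c0) sum(checkLoss(y - c0, 0.5)),
                          numeric(1)))
  expect_equal(sum(checkLoss(y - fit1$intercepts, 0.5)), bruteBest,
               tolerance = 1e-9)

  # full grid: each intercept attains the per-tau brute-force minimum
  fitG <- fitCQROTU(y, X0, b)
  for (s in seq_along(fitG$taus)) {
    attained <- sum(checkLoss(y - fitG$intercepts[s], fitG$taus[s]))
    brute <- min(vapply(sort(unique(y)),
                        function(c0) sum(checkLoss(y - c0, fitG$taus[s])),
                        numeric(1)))
    expect_lt(attained - brute, 1e-9)
  }
  expect_equal(fitG$intercepts,
               unname(quantile(y, fitG$taus, type = 1)))
})

test_that("composite optimiser beats a coarse grid-search oracle on toys", {
  set.seed(23)
  taus <- tauGrid(5)
  for (rep in 1:4) {
    n <- 30
    x <- rnorm(n)
    y <- round(10 + 3 * x + rexp(n, 0.3)) + 1
    y <- pmax(y, 1)
    S <- cbind(x1 = x)
    fit <- fitCQROTU(y, S, factor(rep("g", n)), taus = taus)
    # oracle: scan slope coarsely; optimal intercepts given a slope are
    # residual quantiles
    oracleBest <- min(vapply(seq(-1, 7, by = 0.1), function(a) {
      b <- unname(quantile(y - a * x, taus, type = 1))
      bruteCQRObjective(y, S, taus, b, a)
    }, numeric(1)))
    expect_lte(fit$objective, oracleBest + 1e-6)
  }
})

test_that("single-tau fits match the quantreg oracle objective", {
  skip_if_not_installed("quantreg")
  set.seed(41)
  n <- 120
  x <- rnorm(n)
  g <- factor(rep(c("A", "B"), each = n / 2))
  y <- pmax(1, round(20 + 4 * x + 6 * (g == "B") + rnbinom(n, mu = 8,
                                                           size = 2)))
  S <- cbind(x1 = x)
  for (tau in c(0.25, 0.5, 0.75)) {
    ours <- fitCQROTU(y, S, g, taus = tau, mode = "per_tau")
    rqFit <- suppressWarnings(quantreg::rq(y ~ x + g, tau = tau))
    rqObj <- sum(checkLoss(residuals(rqFit), tau))
    # smoothed optimiser vs exact LP: agree to 1e-5 relative
    expect_lte(ours$objective, rqObj + 1e-5 * max(1, rqObj))
  }
})

test_that("composite objective never exceeds the empirical fallback's", {
  set.seed(59)
  for (rep in 1:5) {
    n <- 90
    x <- rnorm(n)
    g <- factor(rep(c("A", "B", "C"), each = n / 3))
    y <- pmax(1, round(15 + 2 * x + c(A = 0, B = 4, C = -3)[g] +
                         rnbinom(n, mu = 6, size = 1)))
    S <- cbind(x1 = x)
    taus <- tauGrid(9)
    fit <- fitCQROTU(y, S, g, taus = taus)
    grid <- vapply(levels(g), function(lv)
      unname(quantile(y[g == lv], taus, type = 1)), numeric(length(taus)))
    fallbackObj <- sum(vapply(seq_along(taus), function(s)
      sum(checkLoss(y - grid[s, as.character(g)], taus[s])), numeric(1)))
    expect_lte(fit$objective, fallbackObj + 1e-6 * max(1, fallbackObj))
  }
})

test_that("predicted quantiles interpolate the grid, never cross, and shift linearly in batch", {
  set.seed(67)
  n <- 100
  x <- rnorm(n)
  g <- factor(rep(c("A", "B"), each = n / 2))
  y <- pmax(1, round(12 + 3 * x + 5 * (g == "B") +
                       rnbinom(n, mu = 5, size = 2)))
  S <- cbind(x1 = x)
  fit <- fitCQROTU(y, S, g, refLevel = "A")

  v <- predictQuantile(fit, c(x1 = 0.3), "B", fit$taus)
  expect_true(all(diff(v) >= 0))                       # no crossing
  expect_equal(predictQuantile(fit, c(x1 = 0.3), "B", fit$taus[7]), v[7])

  tt <- sort(runif(25, 0.03, 0.97))
  expect_true(all(diff(predictQuantile(fit, c(x1 = -1), "A", tt)) >= -1e-12))

  # composite mode: own-vs-reference difference is exactly delta at
  # every tau (where neither context hits the positive floor)
  vA <- predictQuantile(fit, c(x1 = 0.3), "A", fit$taus)
  vB <- predictQuantile(fit, c(x1 = 0.3), "B", fit$taus)
  free <- vA > fit$minPositive & vB > fit$minPositive
  expect_true(any(free))
  expect_equal(unname((vB - vA)[free]),
               rep(unname(fit$delta["B"]), sum(free)), tolerance = 1e-9)
})

test_that("tiny samples fall back to per-batch empirical quantiles", {
  y <- c(2, 5, 9, 4, 7, 11)
  g <- factor(rep(c("A", "B"), each = 3))
  fit <- fitCQROTU(y, matrix(numeric(0), 6, 0), g)
  expect_identical(fit$method, "empirical")
  expect_true(fit$fallback)
  expect_equal(unname(fit$gridByBatch[10, ]),
               unname(c(quantile(y[1:3], 0.5, type = 1),
                        quantile(y[4:6], 0.5, type = 1))))
})

test_that("the zero-inflated quantile function follows the two-branch rule", {
  taus <- tauGrid(19)
  qf <- ziQuantileFunction(0.6, values = 1:19, taus = taus)
  expect_equal(ziQuantile(qf, 0.3), 0)          # 0.3 < 1 - 0.6
  # (0.7 - 0.4) / 0.6 = 0.5 -> positive branch at its median
  expect_equal(ziQuantile(qf, 0.7), 10)
  # exact branch boundary behaviour
  expect_equal(ziQuantile(qf, 0.4 - 1e-9), 0)
  expect_gt(ziQuantile(qf, 0.4 + 1e-9), 0)
  # no-zero-inflation limit: q -> 1 recovers the positive branch
  qf1 <- ziQuantileFunction(1 - 1e-9, values = 1:19, taus = taus)
  tt <- seq(0.06, 0.94, by = 0.04)
  expect_equal(ziQuantile(qf1, tt),
               approx(taus, 1:19, xout = tt)$y, tolerance = 1e-6)
  # monotone over the whole domain
  grid <- seq(0.01, 0.99, by = 0.005)
  expect_true(all(diff(ziQuantile(qf, grid)) >= 0))
})

test_that("observed values invert to consistent quantile levels", {
  taus <- tauGrid(19)
  qf <- ziQuantileFunction(0.6, values = seq(2, 38, by = 2), taus = taus)
  expect_equal(ziQuantileLevel(qf, 0), 0.2)     # midpoint of zero mass
  # round trip on the continuous stretch of the positive branch
  for (y in c(3, 7.5, 20, 33)) {
    tau <- ziQuantileLevel(qf, y)
    back <- ziQuantile(qf, tau)
    expect_equal(ziQuantileLevel(qf, back), tau, tolerance = 1e-6)
    expect_equal(back, y, tolerance = 1e-9)
  }
  # strictly increasing in y on the positive branch
  ys <- seq(2.5, 37.5, by = 1)
  lv <- vapply(ys, function(y) ziQuantileLevel(qf, y), numeric(1))
  expect_true(all(diff(lv) > 0))
})

test_that("stage 2 is an identity on reference samples and on identical contexts", {
  expt <- makeToyExperiment(n = 20, m = 10, seed = 91, gamma = 0.5,
                            theta = c(0.3, 0.8), psi = c(0.4, -0.4))
  expt <- filterOTUs(expt, 0.1, 3)
  res <- correctBatchEffects(expt, reference = "batch1", seed = 1)
  b <- as.character(batchLabels(expt))
  refCols <- b == "batch1"
  expect_identical(counts(res@corrected)[, refCols],
                   counts(res@stage1)[, refCols])

  # hand-built fits with no batch signal: identical own and reference
  # contexts give back the input up to rounding
  m1 <- counts(res@stage1)
  taus <- tauGrid(19)
  otu <- rownames(m1)[1]
  y <- m1[otu, ]
  zf <- structure(list(coef = c(`(Intercept)` = 0.8),
                       zeta = setNames(numeric(0), character(0)),
                       psi = c(batch1 = 0, batch2 = 0),
                       covNames = character(0),
                       batchLevels = c("batch1", "batch2"),
                       refLevel = "batch1",
                       q = setNames(rep(plogis(0.8), length(y)), names(y)),
                       degenerate = FALSE), class = "zeroFit")
  pos <- y[y > 0]
  cf <- structure(list(method = "composite", taus = taus,
                       intercepts = unname(quantile(pos, taus, type = 1)),
                       alpha = setNames(numeric(0), character(0)),
                       delta = c(batch1 = 0, batch2 = 0),
                       covNames = character(0),
                       batchLevels = c("batch1", "batch2"),
                       refLevel = "batch1", minPositive = min(pos),
                       fallback = FALSE, objective = NA_real_),
                  class = "cqrFit")
  out <- correctNonsystematic(res@stage1,
                              setNames(list(zf), otu),
                              setNames(list(cf), otu), "batch1")
  expect_identical(counts(out)[otu, ], y)
})

test_that("the transport is monotone: larger stage-1 values never shrink past smaller ones", {
  set.seed(8)
  taus <- tauGrid(19)
  vOwn <- sort(round(rlnorm(19, 2, 0.7)) + 1)
  vRef <- sort(round(rlnorm(19, 2.4, 0.5)) + 1)
  for (qs in list(c(0.7, 0.55), c(0.9, 0.9), c(0.5, 0.95))) {
    mapped <- vapply(1:150, function(y)
      CQRBatch:::.transportValue(y, vOwn, vRef, qs[1], qs[2], taus),
      numeric(1))
    expect_true(all(diff(mapped) >= -1e-9))
    # an observed zero never lands above the bulk of the positives
    z0 <- CQRBatch:::.transportValue(0, vOwn, vRef, qs[1], qs[2], taus)
    expect_lte(z0, max(mapped))
  }
})
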