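test_that("robust CV matches hand evaluation and guards zero medians", {
  expect_equal(robustCV(c(5, 5, 5, 5)), 0)
  # median 6, MAD = median(|x - 6|) = median(4,2,0,2,4) = 2
  expect_equal(robustCV(c(2, 4, 6, 8, 10)), 100 * 2 / 6, tolerance = 1e-12)
  expect_true(is.na(robustCV(c(0, 0, 0, 1))))
  expect_error(robustCV(c(1, 2)), "at least 3")
})

test_that("robust CV is scale invariant", {
  set.seed(7)
  for (rep in 1:20) {
    x <- rpois(15, 20) + 1
    c0 <- runif(1, 0.1, 50)
    expect_equal(robustCV(c0 * x), robustCV(x), tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis H matches the rank-sum definition", {
  kw <- kruskalWallis(list(c(1, 2), c(3, 4)))
  expect_equal(kw$statistic, 2.4, tolerance = 1e-12)

  same <- kruskalWallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1)

  const <- kruskalWallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(const$statistic, 0)
  expect_equal(const$p.value, 1)

  set.seed(11)
  for (rep in 1:25) {
    groups <- lapply(1:3, function(i) sample(1:8, sample(3:7, 1),
                                             replace = TRUE))
    expect_equal(kruskalWallis(groups)$statistic, bruteKW(groups),
                 tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(3)
  groups <- lapply(1:3, function(i) rgamma(10, 2))
  h0 <- kruskalWallis(groups)$statistic
  expect_equal(kruskalWallis(lapply(groups, log))$statistic, h0)
  expect_equal(kruskalWallis(lapply(groups, function(x) x^3))$statistic, h0)
})

test_that("homogeneity is near 1 - alpha under the null and near 0 under a shift", {
  set.seed(202)
  n <- 50; m <- 100
  counts <- matrix(rnbinom(m * 2 * n, mu = 30, size = 2), m, 2 * n,
                   dimnames = list(paste0("o", 1:m),
                                   paste0("s", 1:(2 * n))))
  b <- rep(c("A", "B"), each = n)
  bce <- BatchCountExperiment(counts, b)
  hom <- batchHomogeneity(bce, alpha = 0.05)
  expect_true(all(abs(hom - 0.95) < 0.06))

  # batch with a different composition: per-OTU relative abundances
  # alternate far above / far below batch A's
  distorted <- counts
  distorted[, b == "B"] <- matrix(
    rnbinom(m * n, mu = rep(c(4, 150), length.out = m), size = 2), m, n)
  homS <- batchHomogeneity(BatchCountExperiment(distorted, b),
                           alpha = 0.05)
  expect_true(all(homS < 0.05))
})

test_that("reference selection prefers the lower-dispersion batch", {
  set.seed(55)
  n <- 60; m <- 80
  tight <- matrix(rnbinom(m * n, mu = 40, size = 20), m, n)
  loose <- matrix(rnbinom(m * n, mu = 40, size = 1), m, n)
  counts <- cbind(tight, loose)
  dimnames(counts) <- list(paste0("o", 1:m), paste0("s", 1:(2 * n)))
  bce <- BatchCountExperiment(counts, rep(c("tight", "loose"), each = n))
  rep1 <- selectReference(bce)
  expect_s4_class(rep1, "ReferenceReport")
  expect_identical(rep1@selected, "tight")
  expect_lt(rep1@robustCV["tight"], rep1@robustCV["loose"])

  # deterministic given identical input
  rep2 <- selectReference(bce)
  expect_identical(rep1@selected, rep2@selected)
  expect_equal(rep1@homogeneity, rep2@homogeneity)

  forced <- selectReference(bce, force = "loose")
  expect_identical(forced@selected, "loose")
  expect_true(forced@forced)
})
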