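test_that("dissimilarities match their definitions on hand instances", {
  m <- t(matrix(c(2, 0,
                  0, 2,
                  1, 2,
                  3, 2), ncol = 2, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), c("o1", "o2"))))
  bray <- as.matrix(distanceMatrix(m, "bray_curtis"))
  expect_equal(bray["s1", "s2"], 1)                    # (2+2)/(2+2)
  expect_equal(bray["s3", "s4"], 2 / 8)
  canb <- as.matrix(distanceMatrix(m, "canberra"))
  expect_equal(canb["s3", "s4"], 0.5)                  # 2/4 + 0/4
  manh <- as.matrix(distanceMatrix(m, "manhattan"))
  expect_equal(manh["s1", "s2"], 4)

  # identical rows are at distance zero for every metric
  dup <- m[, c(1, 1, 2)]
  colnames(dup) <- c("a", "b", "c")
  for (met in c("bray_curtis", "aitchison", "canberra", "manhattan"))
    expect_equal(as.matrix(distanceMatrix(dup, met))["a", "b"], 0)
})

test_that("canberra skips coordinates that are zero in both samples", {
  m <- t(matrix(c(1, 0, 3,
                  2, 0, 1), ncol = 3, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("o1", "o2", "o3"))))
  d <- as.matrix(distanceMatrix(m, "canberra"))
  expect_equal(d["s1", "s2"], abs(1 - 2) / 3 + abs(3 - 1) / 4)
})

test_that("aitchison equals euclidean distance of CLR coordinates", {
  set.seed(19)
  m <- matrix(rpois(5 * 4, 20), 5, 4,
              dimnames = list(paste0("o", 1:5), paste0("s", 1:4)))
  d <- as.matrix(distanceMatrix(m, "aitchison", pseudocount = 0.5))
  x <- t(m) + 0.5
  x <- x / rowSums(x)
  lx <- log(x); clr <- lx - rowMeans(lx)
  expect_equal(d, as.matrix(dist(clr)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(distanceMatrix(m, "aitchison", pseudocount = 0),
               "pseudocount")
})

test_that("PERMANOVA R2 equals the ANOVA decomposition for 1-D euclidean data", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  d <- dist(pts)
  r <- permanovaR2(d, c("g1", "g1", "g2", "g2"), nPerm = 99, seed = 1)
  expect_equal(r$R2, 100 / 101, tolerance = 1e-10)
})

test_that("PERMANOVA R2 matches vegan::adonis2 and is label-invariant", {
  set.seed(29)
  m <- matrix(rpois(30 * 24, 15), 30, 24,
              dimnames = list(paste0("o", 1:30), paste0("s", 1:24)))
  b <- rep(c("x", "y", "z"), each = 8)
  d <- distanceMatrix(m, "bray_curtis")
  ours <- permanovaR2(d, b, nPerm = 99, seed = 5)
  ad <- vegan::adonis2(d ~ grp, data = data.frame(grp = b),
                       permutations = 99)
  expect_equal(ours$R2, ad$R2[1], tolerance = 1e-10)

  relabeled <- c(x = "BATCH_3", y = "BATCH_1", z = "BATCH_2")[b]
  expect_equal(permanovaR2(d, relabeled, nPerm = 99, seed = 5)$R2, ours$R2)
})

test_that("PERMANOVA p-values are roughly uniform under the null", {
  set.seed(37)
  ps <- replicate(100, {
    m <- matrix(rpois(15 * 20, 10), 15, 20)
    d <- distanceMatrix(m, "bray_curtis")
    permanovaR2(d, rep(c("a", "b"), each = 10), nPerm = 99,
                seed = sample.int(1e6, 1))$p.value
  })
  expect_gt(mean(ps > 0.05), 0.85)
  expect_gt(min(ps), 0)
})

test_that("PCoA embeds euclidean data isometrically", {
  set.seed(43)
  pts <- cbind(rnorm(12), rnorm(12))
  rownames(pts) <- paste0("s", 1:12)
  d <- dist(pts)
  pc <- pcoaCoordinates(d, 2)
  expect_equal(as.matrix(dist(pc$coordinates)), as.matrix(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_lte(sum(pc$eigFractions), 1 + 1e-12)

  # duplicated sample lands on identical coordinates
  d2 <- dist(pts[c(1, 1, 2:12), ])
  pc2 <- pcoaCoordinates(d2, 2)
  expect_equal(pc2$coordinates[1, ], pc2$coordinates[2, ],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("average silhouette matches hand values and the cluster oracle", {
  # points 0,1 | 10,11: outer points score 9.5/10.5, inner 8.5/9.5
  d <- dist(matrix(c(0, 1, 10, 11), ncol = 1))
  s <- avgSilhouette(d, c("a", "a", "b", "b"))
  expect_equal(s, (9.5 / 10.5 + 8.5 / 9.5) / 2, tolerance = 1e-10)

  skip_if_not_installed("cluster")
  set.seed(47)
  pts <- matrix(rnorm(40), ncol = 2)
  lab <- rep(1:4, each = 5)
  dd <- dist(pts)
  oracle <- mean(cluster::silhouette(lab, dd)[, "sil_width"])
  expect_equal(avgSilhouette(dd, lab), oracle, tolerance = 1e-10)
})

test_that("random labels on i.i.d. data give near-zero silhouette", {
  set.seed(53)
  m <- matrix(rpois(40 * 200, 10), 40, 200)
  d <- distanceMatrix(m, "bray_curtis")
  s <- avgSilhouette(d, sample(rep(c("a", "b"), each = 100)))
  expect_lt(abs(s), 0.05)
})

test_that("evaluation of an uncorrected pair is symmetric", {
  expt <- makeToyExperiment(n = 10, m = 8, seed = 3)
  ev <- evaluateCorrection(expt, expt, metrics = c("bray_curtis",
                                                   "manhattan"),
                           nPerm = 99, seed = 2)
  expect_equal(ev$summary$R2.before, ev$summary$R2.after)
  expect_equal(ev$summary$silhouette.before, ev$summary$silhouette.after)
  expect_equal(ev$summary$p.before, ev$summary$p.after)
})
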