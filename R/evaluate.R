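#' @include AllClasses.R
NULL

.METRICS <- c("bray_curtis", "aitchison", "canberra", "manhattan")

#' Centered log-ratio transform
#'
#' Adds a pseudocount, closes each sample to proportions and takes
#' log(x / geometric mean). Rows are samples.
#'
#' @param m matrix with samples as rows, taxa as columns
#' @param pseudocount positive offset added to every cell (default 0.5)
#' @return matrix of CLR coordinates, same shape
#' @export
clrTransform <- function(m, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  x <- m + pseudocount
  x <- x / rowSums(x)
  lx <- log(x)
  lx - rowMeans(lx)
}

#' Between-sample dissimilarity matrix
#'
#' Computes one of the four dissimilarities used by the evaluation
#' suite, on raw counts (Aitchison on CLR-transformed counts):
#' \itemize{
#'   \item \code{bray_curtis}: sum|x - y| / sum(x + y)
#'   \item \code{manhattan}: sum|x - y|
#'   \item \code{canberra}: sum over coordinates with x + y > 0 of
#'     |x - y| / (x + y) (coordinates zero in both samples are
#'     skipped, without rescaling)
#'   \item \code{aitchison}: Euclidean distance of CLR coordinates
#'     (see [clrTransform()])
#' }
#'
#' @param object a \linkS4class{BatchCountExperiment} or a count
#'   matrix with OTUs as rows
#' @param metric one of \code{"bray_curtis"}, \code{"aitchison"},
#'   \code{"canberra"}, \code{"manhattan"}
#' @param pseudocount CLR pseudocount for the Aitchison metric
#' @param relative if TRUE, counts are converted to relative
#'   abundances before Bray-Curtis / Canberra / Manhattan
#' @return a \code{dist} object labelled by sample id
#' @export
distanceMatrix <- function(object, metric = c("bray_curtis", "aitchison",
                                              "canberra", "manhattan"),
                           pseudocount = 0.5, relative = FALSE) {
  metric <- match.arg(metric)
  m <- if (methods::is(object, "BatchCountExperiment")) counts(object)
       else as.matrix(object)
  x <- t(m)  # samples as rows
  if (relative && metric != "aitchison") x <- x / rowSums(x)
  d <- switch(metric,
    bray_curtis = vegan::vegdist(x, method = "bray"),
    manhattan = stats::dist(x, method = "manhattan"),
    aitchison = stats::dist(clrTransform(x, pseudocount),
                            method = "euclidean"),
    canberra = .canberraDist(x))
  attr(d, "metric") <- metric
  d
}

.canberraDist <- function(x) {
  n <- nrow(x)
  out <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    xi <- x[i, ]
    for (j in seq(i + 1, n)) {
      s <- xi + x[j, ]
      keep <- s > 0
      out[i, j] <- out[j, i] <- sum(abs(xi[keep] - x[j, keep]) / s[keep])
    }
  }
  stats::as.dist(out)
}

#' One-factor PERMANOVA R-squared
#'
#' Distance-based decomposition of the total sum of squares into
#' between- and within-group parts (the one-factor adonis statistic):
#' SS_total = sum of squared distances / n, SS_within summed per group,
#' R2 = 1 - SS_within / SS_total. The p-value is obtained by permuting
#' the group labels: p = (1 + #\{F_perm >= F_obs\}) / (1 + nPerm).
#'
#' @param d a \code{dist} object or symmetric matrix
#' @param labels grouping vector, one per sample (>= 2 groups)
#' @param nPerm number of permutations (>= 99; default 999)
#' @param seed integer seed for the permutations
#' @return list with \code{R2}, \code{p.value}, \code{F}
#' @export
permanovaR2 <- function(d, labels, nPerm = 999L, seed = 1L) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  labels <- factor(labels)
  stopifnot(length(labels) == n, nlevels(labels) >= 2, nPerm >= 99)
  ssTotal <- sum(D2) / (2 * n)
  if (ssTotal <= 0) stop("degenerate distance matrix: all points identical")
  ssWithin <- function(lab) {
    sum(vapply(levels(lab), function(g) {
      idx <- which(lab == g)
      sum(D2[idx, idx]) / (2 * length(idx))
    }, numeric(1)))
  }
  k <- nlevels(labels)
  ssw <- ssWithin(labels)
  ssb <- ssTotal - ssw
  R2 <- ssb / ssTotal
  Fobs <- (ssb / (k - 1)) / (ssw / (n - k))
  set.seed(seed)
  Fperm <- vapply(seq_len(nPerm), function(.) {
    lab <- labels[sample.int(n)]
    sswP <- ssWithin(lab)
    ((ssTotal - sswP) / (k - 1)) / (sswP / (n - k))
  }, numeric(1))
  p <- (1 + sum(Fperm >= Fobs)) / (1 + nPerm)
  list(R2 = R2, p.value = p, F = Fobs)
}

#' Principal coordinates analysis
#'
#' Classical MDS of a distance matrix (eigendecomposition of the
#' Gower-centered matrix, via [stats::cmdscale()]). Axes are ordered by
#' eigenvalue; negative eigenvalues are dropped from the embedding and
#' reported.
#'
#' @param d a \code{dist} object or symmetric matrix
#' @param nAxes number of axes to return (default 2)
#' @return list with \code{coordinates} (samples x axes),
#'   \code{eigFractions} (eigenvalue / sum of positive eigenvalues),
#'   \code{negativeEigenvalues}, and \code{truncated} flag when fewer
#'   positive axes exist than requested
#' @export
pcoaCoordinates <- function(d, nAxes = 2L) {
  stopifnot(nAxes >= 1)
  d <- stats::as.dist(as.matrix(d))
  n <- attr(d, "Size")
  fit <- stats::cmdscale(d, k = min(nAxes, n - 1), eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > 1e-12]
  nKeep <- min(nAxes, length(pos), ncol(fit$points))
  coords <- fit$points[, seq_len(nKeep), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(nKeep))
  list(coordinates = coords,
       eigFractions = pos[seq_len(nKeep)] / sum(pos),
       negativeEigenvalues = eig[eig < -1e-12],
       truncated = nKeep < nAxes)
}

#' Average silhouette coefficient
#'
#' For each sample, a = mean distance to its own group (excluding
#' itself), b = smallest mean distance to any other group, and
#' s = (b - a) / max(a, b); singleton groups contribute s = 0 by
#' convention. Near-zero averages indicate indistinct group boundaries
#' -- the desired state after batch correction.
#'
#' @param d a \code{dist} object or symmetric matrix
#' @param labels grouping vector, one per sample (>= 2 groups)
#' @return mean silhouette width in [-1, 1]
#' @export
avgSilhouette <- function(d, labels) {
  D <- as.matrix(d)
  labels <- factor(labels)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  if (nlevels(labels) < 2) stop("at least 2 groups required")
  s <- vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(levels(labels), as.character(labels[i])),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Evaluate batch structure of one count table
#'
#' Runs the full per-metric evaluation: PERMANOVA R2 with permutation
#' p-value, average silhouette over batch labels, and 2-axis PCoA.
#'
#' @param object a \linkS4class{BatchCountExperiment}
#' @param metrics dissimilarities to use (default all four)
#' @param nPerm PERMANOVA permutations
#' @param seed permutation seed
#' @param pseudocount CLR pseudocount for Aitchison
#' @return list with \code{summary} (data.frame: metric, R2, p.value,
#'   silhouette) and \code{pcoa} (named list of per-metric coordinate
#'   data.frames with batch labels)
#' @export
evaluateBatchEffects <- function(object, metrics = .METRICS,
                                 nPerm = 999L, seed = 1L,
                                 pseudocount = 0.5) {
  metrics <- match.arg(metrics, .METRICS, several.ok = TRUE)
  b <- batchLabels(object)
  rows <- list(); pc <- list()
  for (met in metrics) {
    d <- distanceMatrix(object, met, pseudocount)
    pm <- permanovaR2(d, b, nPerm, seed)
    sil <- avgSilhouette(d, b)
    ax <- pcoaCoordinates(d, 2)
    rows[[met]] <- data.frame(metric = met, R2 = pm$R2,
                              p.value = pm$p.value, silhouette = sil)
    pc[[met]] <- data.frame(sample = colnames(object),
                            ax$coordinates, batch = as.character(b))
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       pcoa = pc)
}

#' Compare batch structure before and after correction
#'
#' @param before,after aligned \linkS4class{BatchCountExperiment}s
#'   (same samples, same batches)
#' @inheritParams evaluateBatchEffects
#' @return list with \code{summary} (data.frame: metric, R2.before,
#'   R2.after, p.before, p.after, silhouette.before, silhouette.after)
#'   and \code{pcoa} (per-metric before/after coordinate tables)
#' @export
evaluateCorrection <- function(before, after, metrics = .METRICS,
                               nPerm = 999L, seed = 1L,
                               pseudocount = 0.5) {
  stopifnot(identical(colnames(before), colnames(after)))
  evB <- evaluateBatchEffects(before, metrics, nPerm, seed, pseudocount)
  evA <- evaluateBatchEffects(after, metrics, nPerm, seed, pseudocount)
  s <- data.frame(metric = evB$summary$metric,
                  R2.before = evB$summary$R2, R2.after = evA$summary$R2,
                  p.before = evB$summary$p.value,
                  p.after = evA$summary$p.value,
                  silhouette.before = evB$summary$silhouette,
                  silhouette.after = evA$summary$silhouette)
  list(summary = s,
       pcoa = list(before = evB$pcoa, after = evA$pcoa))
}
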