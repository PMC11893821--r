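#' @include AllClasses.R
NULL

#' Robust coefficient of variation
#'
#' Robust CV = 100 * MAD / median, where MAD is the plain median of
#' absolute deviations from the median (no normal-consistency constant).
#' A robust alternative to the classical CV for skewed, outlier-prone
#' count data.
#'
#' @param values numeric vector of length >= 3
#' @return percent (non-negative), or NA_real_ when the median is not
#'   strictly positive (undefined; never silently dropped upstream)
#' @examples
#' robustCV(c(2, 4, 6, 8, 10))  # 100 * 2 / 6
#' @export
robustCV <- function(values) {
  if (length(values) < 3) stop("robustCV needs at least 3 values")
  med <- stats::median(values)
  if (!is.finite(med) || med <= 0) return(NA_real_)
  mad0 <- stats::median(abs(values - med))
  100 * mad0 / med
}

#' Kruskal-Wallis rank test
#'
#' Thin wrapper around [stats::kruskal.test()] returning the
#' tie-corrected H statistic and a chi-square p-value on
#' (number of groups - 1) degrees of freedom. When all pooled values
#' are identical the statistic is defined as 0 with p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty)
#' @return list with elements \code{statistic} and \code{p.value}
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2) stop("kruskalWallis needs at least 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group supplied")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1)
    return(list(statistic = 0, p.value = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), p.value = unname(kt$p.value))
}

#' Per-batch distributional homogeneity
#'
#' Screens every batch for distributional agreement with every other
#' batch: for each ordered batch pair (g, h) and each correctable OTU,
#' a two-group Kruskal-Wallis test is run on the relative abundances
#' (count / library size, zeros included) of batch g versus batch h.
#' The homogeneity of batch g is the fraction of its (OTU, other-batch)
#' comparisons with p >= alpha; values near 1 indicate a batch whose
#' OTU distributions blend with the rest of the study.
#'
#' @param object a \linkS4class{BatchCountExperiment}, ideally after
#'   [filterOTUs()]
#' @param alpha significance level for "different" (default 0.05)
#' @return named numeric vector of per-batch fractions in [0, 1]
#' @export
batchHomogeneity <- function(object, alpha = 0.05) {
  b <- batchLabels(object)
  lv <- levels(b)
  if (length(lv) < 2) stop("at least 2 batches required")
  keep <- correctableOTUs(object)
  rel <- sweep(counts(object)[keep, , drop = FALSE], 2,
               librarySizes(object), "/")
  nonSig <- matrix(NA_real_, length(lv), length(lv),
                   dimnames = list(lv, lv))
  for (a in seq_along(lv)) for (h in seq_along(lv)) {
    if (h <= a) next
    xa <- rel[, b == lv[a], drop = FALSE]
    xh <- rel[, b == lv[h], drop = FALSE]
    p <- vapply(seq_len(nrow(rel)), function(j)
      kruskalWallis(list(xa[j, ], xh[j, ]))$p.value, numeric(1))
    nonSig[a, h] <- nonSig[h, a] <- mean(p >= alpha)
  }
  vapply(lv, function(g) mean(nonSig[g, setdiff(lv, g)]), numeric(1))
}

#' Select the reference batch
#'
#' Two-step data-driven selection of the batch whose OTU distributions
#' all other batches are aligned to. First, batches are screened for
#' homogeneity with [batchHomogeneity()] and shortlisted (default:
#' batches at or above the median homogeneity; alternatively a fixed
#' threshold). Second, for each shortlisted batch the robust CV
#' ([robustCV()]) of each OTU's non-zero counts within the batch is
#' computed (OTUs with fewer than 3 non-zero values in the batch are
#' skipped) and aggregated by the median across OTUs; the shortlisted
#' batch with the smallest aggregate robust CV wins. Ties are broken by
#' larger batch size, then lexicographic label.
#'
#' @param object a \linkS4class{BatchCountExperiment} (run
#'   [filterOTUs()] first for a stable screen)
#' @param alpha significance level for the homogeneity screen
#' @param shortlistRule \code{"top_half"} (default; homogeneity >=
#'   median homogeneity) or \code{"threshold"} (homogeneity >=
#'   \code{threshold})
#' @param threshold homogeneity cut-off for
#'   \code{shortlistRule = "threshold"} (default 0.9)
#' @param force a batch label overriding the data-driven choice; the
#'   report is still computed and flags the override
#' @return a \linkS4class{ReferenceReport}
#' @export
selectReference <- function(object, alpha = 0.05,
                            shortlistRule = c("top_half", "threshold"),
                            threshold = 0.9, force = NULL) {
  shortlistRule <- match.arg(shortlistRule)
  b <- batchLabels(object)
  lv <- levels(b)
  if (length(lv) < 2) stop("at least 2 batches required")
  hom <- batchHomogeneity(object, alpha)
  shortlist <- if (shortlistRule == "top_half")
    lv[hom >= stats::median(hom)] else lv[hom >= threshold]
  if (!length(shortlist)) shortlist <- lv[which.max(hom)]
  keep <- correctableOTUs(object)
  m <- counts(object)[keep, , drop = FALSE]
  cv <- vapply(lv, function(g) {
    sub <- m[, b == g, drop = FALSE]
    perOTU <- apply(sub, 1, function(y) {
      y <- y[y > 0]
      if (length(y) < 3) return(NA_real_)
      robustCV(y)
    })
    perOTU <- perOTU[!is.na(perOTU)]
    if (!length(perOTU)) NA_real_ else stats::median(perOTU)
  }, numeric(1))
  cand <- cv[shortlist]
  if (all(is.na(cand)))
    stop("robust CV undefined for every shortlisted batch; ",
         "choose a reference manually via 'force'")
  ord <- order(cand, -as.numeric(table(b)[shortlist]), shortlist,
               na.last = TRUE)
  selected <- shortlist[ord[1]]
  forced <- FALSE
  if (!is.null(force)) {
    force <- as.character(force)
    if (!force %in% lv)
      stop("forced reference '", force, "' is not a batch label")
    selected <- force
    forced <- TRUE
  }
  methods::new("ReferenceReport", homogeneity = hom, robustCV = cv,
               shortlist = shortlist, selected = selected,
               alpha = alpha, forced = forced)
}
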