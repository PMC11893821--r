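#' @importFrom methods new validObject is setClass setGeneric setMethod
#'   setValidity show slot
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData rowData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' BatchCountExperiment: an OTU count table with batch structure
#'
#' An S4 container for a microbiome OTU count matrix together with the
#' study design needed for batch effect correction: a batch label per
#' sample, covariate columns, and (optionally) a designated reference
#' batch. It extends \linkS4class{SummarizedExperiment}; rows are OTUs,
#' columns are samples, and the single assay \code{"counts"} holds
#' non-negative integer read counts.
#'
#' Validity requires: integral non-negative counts; no sample with zero
#' library size (all-zero column); unique row and column names; a
#' \code{batch} column in \code{colData}; and every covariate name
#' present in \code{colData}.
#'
#' @slot covariateNames character vector naming the \code{colData}
#'   columns used as covariates (may be empty).
#' @slot referenceBatch character; the designated reference batch label,
#'   or \code{character(0)} when unset.
#'
#' @seealso [BatchCountExperiment()] for the constructor,
#'   [counts()], [batchLabels()], [librarySizes()], [covariateMatrix()],
#'   [batchIndicators()], [referenceBatch()].
#' @export
setClass("BatchCountExperiment",
  contains = "SummarizedExperiment",
  representation(
    covariateNames = "character",
    referenceBatch = "character"
  )
)

setValidity("BatchCountExperiment", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is missing")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(is.na(m)))
    msg <- c(msg, "counts contain missing values")
  else {
    if (any(m < 0)) msg <- c(msg, "counts contain negative values")
    if (any(m != round(m))) msg <- c(msg, "counts contain non-integral values")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "OTU ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (!"batch" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'batch' column")
  cn <- object@covariateNames
  missingCov <- setdiff(cn, colnames(SummarizedExperiment::colData(object)))
  if (length(missingCov))
    msg <- c(msg, paste0("covariate columns not in colData: ",
                         paste(missingCov, collapse = ", ")))
  if (length(object@referenceBatch) > 1)
    msg <- c(msg, "referenceBatch must be a single label or unset")
  if (length(object@referenceBatch) == 1 &&
      !object@referenceBatch %in%
        as.character(SummarizedExperiment::colData(object)$batch))
    msg <- c(msg, "referenceBatch is not one of the batch labels")
  if (length(msg)) msg else TRUE
})

#' Construct a BatchCountExperiment
#'
#' @param counts non-negative integer matrix of read counts. Orientation
#'   is declared with \code{orientation}; internally OTUs are stored as
#'   rows and samples as columns.
#' @param batch vector of batch labels, one per sample, named by sample
#'   id or in sample order.
#' @param covariates data.frame (or DataFrame) of per-sample covariates,
#'   or NULL for none. Row order / rownames must correspond to samples.
#' @param orientation either \code{"otus_by_samples"} (rows are OTUs) or
#'   \code{"samples_by_otus"} (rows are samples; the matrix is
#'   transposed on the way in).
#' @param minBatchSize smallest admissible batch (default 3); a batch
#'   with fewer samples is an error.
#' @return a validated \linkS4class{BatchCountExperiment}
#' @examples
#' m <- matrix(rpois(30, 5) + 1L, nrow = 5,
#'             dimnames = list(paste0("otu", 1:5), paste0("s", 1:6)))
#' bce <- BatchCountExperiment(m, batch = rep(c("A", "B"), each = 3))
#' librarySizes(bce)
#' @export
BatchCountExperiment <- function(counts, batch, covariates = NULL,
                                 orientation = c("otus_by_samples",
                                                 "samples_by_otus"),
                                 minBatchSize = 3L) {
  orientation <- match.arg(orientation)
  counts <- as.matrix(counts)
  if (orientation == "samples_by_otus") counts <- t(counts)
  storage.mode(counts) <- "double"
  .checkIntegerCounts(counts)
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("samples with zero library size are rejected: ",
         paste(colnames(counts)[zero], collapse = ", "))
  storage.mode(counts) <- "integer"
  batch <- as.character(batch)
  if (length(batch) != ncol(counts))
    stop("'batch' must have one label per sample (", ncol(counts),
         " samples, ", length(batch), " labels)")
  if (anyNA(batch)) stop("batch labels contain missing values")
  tooSmall <- table(batch) < minBatchSize
  if (any(tooSmall))
    stop("batches with fewer than ", minBatchSize, " samples: ",
         paste(names(which(tooSmall)), collapse = ", "))
  cd <- S4Vectors::DataFrame(batch = factor(batch), row.names = colnames(counts))
  covNames <- character(0)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != ncol(counts))
      stop("covariates must have one row per sample")
    bad <- names(covariates)[vapply(covariates, anyNA, logical(1))]
    if (length(bad))
      stop("missing covariate values in column(s): ",
           paste(bad, collapse = ", "))
    covNames <- names(covariates)
    for (nm in covNames) cd[[nm]] <- covariates[[nm]]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  methods::new("BatchCountExperiment", se,
               covariateNames = covNames, referenceBatch = character(0))
}

.checkIntegerCounts <- function(m) {
  if (any(is.na(m))) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing count at row '", rownames(m)[idx[1]], "', column '",
         colnames(m)[idx[2]], "'")
  }
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-integer or negative count at row '",
         rownames(m)[bad[1, 1]], "', column '", colnames(m)[bad[1, 2]],
         "' (value ", m[bad[1, 1], bad[1, 2]], ")")
  }
  invisible(TRUE)
}

#' ReferenceReport: result of reference batch selection
#'
#' @slot homogeneity named numeric, per-batch fraction of pairwise
#'   per-OTU Kruskal-Wallis comparisons that were non-significant.
#' @slot robustCV named numeric, per-batch aggregate robust coefficient
#'   of variation (percent; median over OTUs); NA when undefined.
#' @slot shortlist character, batches passing the homogeneity screen.
#' @slot selected character, the chosen reference batch.
#' @slot alpha numeric, significance level used in screening.
#' @slot forced logical, TRUE when the user overrode the selection.
#' @seealso [selectReference()]
#' @export
setClass("ReferenceReport",
  representation(
    homogeneity = "numeric",
    robustCV = "numeric",
    shortlist = "character",
    selected = "character",
    alpha = "numeric",
    forced = "logical"
  )
)

setValidity("ReferenceReport", function(object) {
  msg <- character(0)
  if (length(object@selected) != 1)
    msg <- c(msg, "exactly one selected batch required")
  if (!length(object@shortlist))
    msg <- c(msg, "shortlist must be non-empty")
  if (length(object@selected) == 1 && !object@forced &&
      !object@selected %in% object@shortlist)
    msg <- c(msg, "selected batch must belong to the shortlist")
  cv <- object@robustCV
  if (any(!is.na(cv) & cv < 0))
    msg <- c(msg, "robust CV values must be >= 0 or NA (undefined)")
  if (length(msg)) msg else TRUE
})

#' BatchCorrection: full result of the two-stage correction
#'
#' Returned by [correctBatchEffects()]. Holds the final corrected table,
#' the intermediate stage-1 (negative binomial adjusted) table, the
#' per-OTU fit records of all three models, the reference selection
#' report, and provenance (resolved parameters and seed).
#'
#' @slot corrected \linkS4class{BatchCountExperiment} after both stages.
#' @slot stage1 \linkS4class{BatchCountExperiment} after the negative
#'   binomial stage only.
#' @slot input \linkS4class{BatchCountExperiment} as supplied (aligned,
#'   filtered flags in rowData).
#' @slot nbFits list of per-OTU negative binomial fit records.
#' @slot zeroFits list of per-OTU logistic presence fit records.
#' @slot cqrFits list of per-OTU composite quantile regression records.
#' @slot referenceReport \linkS4class{ReferenceReport} or NULL-like
#'   placeholder when the reference was forced.
#' @slot provenance list echoing the resolved configuration.
#' @export
setClass("BatchCorrection",
  representation(
    corrected = "BatchCountExperiment",
    stage1 = "BatchCountExperiment",
    input = "BatchCountExperiment",
    nbFits = "list",
    zeroFits = "list",
    cqrFits = "list",
    referenceReport = "ANY",
    provenance = "list"
  )
)

setValidity("BatchCorrection", function(object) {
  msg <- character(0)
  if (!identical(dim(object@corrected), dim(object@input)))
    msg <- c(msg, "corrected table must match the input shape")
  if (!identical(dimnames(object@corrected), dimnames(object@input)))
    msg <- c(msg, "corrected table must keep input sample and OTU ids")
  if (length(msg)) msg else TRUE
})
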