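#' @include AllClasses.R
NULL

#' Access the count matrix
#'
#' Method for the \pkg{BiocGenerics} \code{counts} generic.
#'
#' @param object a \linkS4class{BatchCountExperiment}
#' @param ... ignored
#' @return integer matrix, OTUs in rows, samples in columns
#' @importFrom BiocGenerics counts
#' @export counts
#' @aliases counts
#' @name counts
#' @export
setMethod("counts", "BatchCountExperiment", function(object, ...)
  SummarizedExperiment::assay(object, "counts"))

#' Per-sample batch labels
#'
#' @param object a \linkS4class{BatchCountExperiment}
#' @return factor of batch labels, one per sample
#' @export
setGeneric("batchLabels", function(object) standardGeneric("batchLabels"))

#' @rdname batchLabels
#' @export
setMethod("batchLabels", "BatchCountExperiment", function(object) {
  b <- SummarizedExperiment::colData(object)$batch
  factor(as.character(b))
})

#' Per-sample library sizes
#'
#' Library size is the total read count of a sample across all OTUs
#' (the column sum), used as the offset N_i in the negative binomial
#' stage.
#'
#' @param object a \linkS4class{BatchCountExperiment}
#' @return named integer vector of column sums
#' @export
setGeneric("librarySizes", function(object) standardGeneric("librarySizes"))

#' @rdname librarySizes
#' @export
setMethod("librarySizes", "BatchCountExperiment", function(object)
  colSums(counts(object)))

#' Encoded covariate matrix
#'
#' Builds the numeric covariate matrix X used by every model stage.
#' Numeric covariates pass through; categorical covariates are
#' dummy-encoded with the first lexicographic level as the reference
#' level. No intercept column is included. The result has full column
#' rank (rank deficiency is an error).
#'
#' @param object a \linkS4class{BatchCountExperiment}
#' @return numeric matrix with one row per sample (zero columns when the
#'   design has no covariates)
#' @export
setGeneric("covariateMatrix", function(object)
  standardGeneric("covariateMatrix"))

#' @rdname covariateMatrix
#' @export
setMethod("covariateMatrix", "BatchCountExperiment", function(object) {
  cn <- object@covariateNames
  n <- ncol(object)
  if (!length(cn))
    return(matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(colnames(object), NULL)))
  cd <- as.data.frame(SummarizedExperiment::colData(object))[, cn, drop = FALSE]
  for (nm in names(cd)) {
    if (is.character(cd[[nm]]) || is.logical(cd[[nm]]))
      cd[[nm]] <- factor(cd[[nm]], levels = sort(unique(as.character(cd[[nm]]))))
    else if (is.factor(cd[[nm]]))
      cd[[nm]] <- factor(as.character(cd[[nm]]),
                         levels = sort(unique(as.character(cd[[nm]]))))
  }
  X <- stats::model.matrix(~ ., data = cd)[, -1, drop = FALSE]
  rownames(X) <- colnames(object)
  if (ncol(X) > 0 && qr(X)$rank < ncol(X))
    stop("covariate matrix is rank deficient after encoding")
  X
})

#' One-hot batch indicator matrix
#'
#' @param object a \linkS4class{BatchCountExperiment}
#' @return 0/1 matrix, one row per sample, one column per batch level;
#'   rows sum to 1
#' @export
setGeneric("batchIndicators", function(object)
  standardGeneric("batchIndicators"))

#' @rdname batchIndicators
#' @export
setMethod("batchIndicators", "BatchCountExperiment", function(object) {
  b <- batchLabels(object)
  B <- stats::model.matrix(~ 0 + b)
  colnames(B) <- levels(b)
  rownames(B) <- colnames(object)
  B
})

#' Get or set the designated reference batch
#'
#' @param object a \linkS4class{BatchCountExperiment}
#' @param value a batch label present in the design
#' @return the reference batch label, or NA when unset
#' @export
setGeneric("referenceBatch", function(object)
  standardGeneric("referenceBatch"))

#' @rdname referenceBatch
#' @export
setMethod("referenceBatch", "BatchCountExperiment", function(object)
  if (length(object@referenceBatch)) object@referenceBatch else NA_character_)

#' @rdname referenceBatch
#' @export
setGeneric("referenceBatch<-", function(object, value)
  standardGeneric("referenceBatch<-"))

#' @rdname referenceBatch
#' @export
setMethod("referenceBatch<-", "BatchCountExperiment", function(object, value) {
  value <- as.character(value)
  if (length(value) != 1 || !value %in% levels(batchLabels(object)))
    stop("reference batch must be one of: ",
         paste(levels(batchLabels(object)), collapse = ", "))
  object@referenceBatch <- value
  methods::validObject(object)
  object
})

#' OTUs eligible for correction
#'
#' Returns the logical flag written by [filterOTUs()] (rowData column
#' \code{correctable}); TRUE for every OTU when the filter has not been
#' applied.
#'
#' @param object a \linkS4class{BatchCountExperiment}
#' @return named logical vector, one element per OTU
#' @export
setGeneric("correctableOTUs", function(object)
  standardGeneric("correctableOTUs"))

#' @rdname correctableOTUs
#' @export
setMethod("correctableOTUs", "BatchCountExperiment", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  out <- if ("correctable" %in% colnames(rd)) rd$correctable
         else rep(TRUE, nrow(object))
  names(out) <- rownames(object)
  out
})

#' @describeIn BatchCountExperiment-class compact display
#' @param object a \linkS4class{BatchCountExperiment}
#' @export
setMethod("show", "BatchCountExperiment", function(object) {
  b <- batchLabels(object)
  cat("BatchCountExperiment:", nrow(object), "OTUs x", ncol(object),
      "samples\n")
  cat("  batches:", paste(sprintf("%s(%d)", levels(b), table(b)),
                          collapse = " "), "\n")
  cat("  covariates:",
      if (length(object@covariateNames))
        paste(object@covariateNames, collapse = ", ") else "(none)", "\n")
  cat("  reference batch:",
      if (length(object@referenceBatch)) object@referenceBatch else "(unset)",
      "\n")
  zf <- mean(counts(object) == 0)
  cat(sprintf("  zero fraction: %.1f%%; library sizes %d-%d\n",
              100 * zf, min(librarySizes(object)),
              max(librarySizes(object))))
})

#' @describeIn ReferenceReport-class compact display
#' @param object a \linkS4class{ReferenceReport}
#' @export
setMethod("show", "ReferenceReport", function(object) {
  cat("ReferenceReport (alpha =", object@alpha, ")\n")
  tab <- data.frame(
    batch = names(object@homogeneity),
    homogeneity = round(object@homogeneity, 4),
    robustCV = round(object@robustCV[names(object@homogeneity)], 2),
    shortlisted = names(object@homogeneity) %in% object@shortlist)
  print(tab, row.names = FALSE)
  cat("selected:", object@selected,
      if (object@forced) "(forced by user)" else "", "\n")
})

#' @describeIn BatchCorrection-class compact display
#' @param object a \linkS4class{BatchCorrection}
#' @export
setMethod("show", "BatchCorrection", function(object) {
  cat("BatchCorrection:", nrow(object@corrected), "OTUs x",
      ncol(object@corrected), "samples\n")
  cat("  reference batch:", object@provenance$reference, "\n")
  cat("  corrected OTUs:", sum(correctableOTUs(object@input)), "of",
      nrow(object@input), "\n")
  conv <- vapply(object@nbFits, function(f) isTRUE(f$converged), logical(1))
  if (length(conv))
    cat("  stage-1 NB fits converged:", sum(conv), "of", length(conv), "\n")
  cat("  mode:", object@provenance$mode,
      "| quantile grid k =", object@provenance$k, "\n")
})

#' Final corrected count table
#' @param object a \linkS4class{BatchCorrection}
#' @return a \linkS4class{BatchCountExperiment}
#' @export
setGeneric("correctedExperiment", function(object)
  standardGeneric("correctedExperiment"))

#' @rdname correctedExperiment
#' @export
setMethod("correctedExperiment", "BatchCorrection", function(object)
  object@corrected)

#' Stage-1 (negative binomial adjusted) count table
#' @param object a \linkS4class{BatchCorrection}
#' @return a \linkS4class{BatchCountExperiment}
#' @export
setGeneric("stage1Experiment", function(object)
  standardGeneric("stage1Experiment"))

#' @rdname stage1Experiment
#' @export
setMethod("stage1Experiment", "BatchCorrection", function(object)
  object@stage1)
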