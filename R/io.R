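#' @include AllClasses.R
NULL

.readDelimAuto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "\"")
}

#' Read an OTU count table from delimited text
#'
#' The file must have a header row and an id column as its first column.
#' With \code{orientation = "samples_by_otus"} rows are samples and the
#' header names OTUs; with \code{"otus_by_samples"} the file is
#' transposed on the way in. Cells must be non-negative integers; the
#' first offending cell is named in the error.
#'
#' @param path path to a TSV or CSV file (delimiter sniffed from the
#'   header line)
#' @param orientation file layout, see Description
#' @return integer matrix with OTUs as rows and samples as columns
#' @seealso [BatchCountExperiment()], [writeCountTable()]
#' @export
readCountTable <- function(path,
                           orientation = c("samples_by_otus",
                                           "otus_by_samples")) {
  orientation <- match.arg(orientation)
  df <- .readDelimAuto(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate column ids in '", path, "'")
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow = nrow(m)))) , arr.ind = TRUE)
    stop("non-numeric count at row '", ids[bad[1, 1]], "', column '",
         colnames(m)[bad[1, 2]], "'")
  }
  rownames(m) <- ids
  if (orientation == "samples_by_otus") m <- t(m)
  .checkIntegerCounts(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count table as TSV
#'
#' @param object a \linkS4class{BatchCountExperiment} or a count matrix
#'   (OTUs x samples)
#' @param path output file
#' @param orientation layout of the written file (see
#'   [readCountTable()])
#' @return invisibly, the path
#' @export
writeCountTable <- function(object, path,
                            orientation = c("samples_by_otus",
                                            "otus_by_samples")) {
  orientation <- match.arg(orientation)
  m <- if (methods::is(object, "BatchCountExperiment")) counts(object)
       else as.matrix(object)
  if (orientation == "samples_by_otus") m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- if (orientation == "samples_by_otus") "sample_id"
                  else "otu_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a delimited metadata file and extracts the batch label and the
#' requested covariate columns. Missing covariate values are an error
#' (no imputation); batches smaller than \code{minBatchSize} are an
#' error.
#'
#' @param path TSV/CSV file with a header
#' @param batchColumn name of the batch label column
#' @param covariateColumns character vector of covariate column names
#'   (may be empty)
#' @param sampleColumn name of the sample id column; default is the
#'   first column
#' @param minBatchSize smallest admissible batch (default 3)
#' @return data.frame with rownames = sample ids, a \code{batch} column
#'   and the covariate columns
#' @export
readMetadata <- function(path, batchColumn, covariateColumns = character(0),
                         sampleColumn = NULL, minBatchSize = 3L) {
  df <- .readDelimAuto(path)
  if (is.null(sampleColumn)) sampleColumn <- names(df)[1]
  need <- c(sampleColumn, batchColumn, covariateColumns)
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop("metadata columns not found: ", paste(absent, collapse = ", "))
  ids <- as.character(df[[sampleColumn]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- data.frame(batch = as.character(df[[batchColumn]]),
                    row.names = ids, check.names = FALSE)
  for (nm in covariateColumns) {
    v <- df[[nm]]
    if (anyNA(v) || any(v == "", na.rm = TRUE)) {
      bad <- ids[is.na(v) | v == ""]
      stop("missing values for covariate '", nm, "' in sample(s): ",
           paste(bad, collapse = ", "))
    }
    out[[nm]] <- v
  }
  if (anyNA(out$batch) || any(out$batch == ""))
    stop("missing batch labels in metadata")
  tooSmall <- table(out$batch) < minBatchSize
  if (any(tooSmall))
    stop("batches with fewer than ", minBatchSize, " samples: ",
         paste(names(which(tooSmall)), collapse = ", "))
  out
}

#' Align a count matrix and a metadata table by sample id
#'
#' Restricts both to the intersection of sample ids, in the count
#' table's sample order. Dropped samples are reported via message().
#'
#' @param counts count matrix, OTUs x samples (as from
#'   [readCountTable()])
#' @param metadata data.frame with sample ids as rownames (as from
#'   [readMetadata()])
#' @return list with elements \code{counts} and \code{metadata},
#'   identically ordered
#' @export
alignSamples <- function(counts, metadata) {
  common <- intersect(colnames(counts), rownames(metadata))
  if (!length(common))
    stop("no sample ids shared between count table and metadata")
  droppedCounts <- setdiff(colnames(counts), common)
  droppedMeta <- setdiff(rownames(metadata), common)
  if (length(droppedCounts))
    message("dropping ", length(droppedCounts),
            " count-table sample(s) absent from metadata: ",
            paste(utils::head(droppedCounts, 5), collapse = ", "),
            if (length(droppedCounts) > 5) ", ...")
  if (length(droppedMeta))
    message("dropping ", length(droppedMeta),
            " metadata sample(s) absent from count table: ",
            paste(utils::head(droppedMeta, 5), collapse = ", "),
            if (length(droppedMeta) > 5) ", ...")
  keep <- colnames(counts)[colnames(counts) %in% common]
  list(counts = counts[, keep, drop = FALSE],
       metadata = metadata[keep, , drop = FALSE])
}

#' Read count table and metadata into a BatchCountExperiment
#'
#' Convenience wrapper: [readCountTable()] + [readMetadata()] +
#' [alignSamples()] + [BatchCountExperiment()].
#'
#' @inheritParams readCountTable
#' @inheritParams readMetadata
#' @param countPath count table file
#' @param metadataPath metadata file
#' @return a \linkS4class{BatchCountExperiment}
#' @export
readBatchCountExperiment <- function(countPath, metadataPath, batchColumn,
                                     covariateColumns = character(0),
                                     orientation = c("samples_by_otus",
                                                     "otus_by_samples"),
                                     sampleColumn = NULL,
                                     minBatchSize = 3L) {
  m <- readCountTable(countPath, match.arg(orientation))
  meta <- readMetadata(metadataPath, batchColumn, covariateColumns,
                       sampleColumn, minBatchSize = 1L)
  al <- alignSamples(m, meta)
  BatchCountExperiment(al$counts, batch = al$metadata$batch,
                       covariates = al$metadata[, covariateColumns,
                                                drop = FALSE],
                       minBatchSize = minBatchSize)
}

#' Flag OTUs eligible for model-based correction
#'
#' Per-batch negative binomial and quantile fits need enough non-zero
#' observations in every batch to be well posed. An OTU is flagged
#' correctable when its overall non-zero fraction is at least
#' \code{minPrevalence} AND it has at least \code{minNonzeroPerBatch}
#' non-zero samples in every batch. Flagged-out OTUs are kept in the
#' table and passed through the correction untouched.
#'
#' @param object a \linkS4class{BatchCountExperiment}
#' @param minPrevalence minimum overall non-zero fraction in [0, 1]
#'   (default 0.1)
#' @param minNonzeroPerBatch minimum non-zero samples per batch
#'   (default 3)
#' @return the object with a logical \code{correctable} column in
#'   rowData
#' @export
filterOTUs <- function(object, minPrevalence = 0.1,
                       minNonzeroPerBatch = 3L) {
  stopifnot(minPrevalence >= 0, minPrevalence <= 1)
  m <- counts(object)
  b <- batchLabels(object)
  nz <- m > 0
  prev <- rowMeans(nz)
  perBatch <- vapply(levels(b), function(g)
    rowSums(nz[, b == g, drop = FALSE]), numeric(nrow(m)))
  if (nrow(m) == 1) perBatch <- matrix(perBatch, nrow = 1)
  keep <- prev >= minPrevalence &
    apply(perBatch >= minNonzeroPerBatch, 1, all)
  if (!any(keep))
    stop("no OTU passes the prevalence filter (minPrevalence = ",
         minPrevalence, ", minNonzeroPerBatch = ", minNonzeroPerBatch, ")")
  rd <- SummarizedExperiment::rowData(object)
  rd$correctable <- unname(keep)
  SummarizedExperiment::rowData(object) <- rd
  object
}
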