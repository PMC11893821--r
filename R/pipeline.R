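#' @include AllClasses.R
NULL

#' Run the full two-stage batch correction
#'
#' End-to-end correction of a \linkS4class{BatchCountExperiment}:
#' prevalence filtering ([filterOTUs()]), reference batch selection
#' ([selectReference()], unless forced), stage 1 negative binomial
#' adjustment ([correctSystematic()]), stage 2 presence +
#' composite-quantile modelling ([fitZeroOTU()], [fitCQROTU()]) and
#' transport onto the reference batch ([correctNonsystematic()]).
#'
#' @param object a \linkS4class{BatchCountExperiment}
#' @param reference \code{"auto"} (data-driven selection) or a batch
#'   label
#' @param alpha significance level of the homogeneity screen
#' @param k size of the quantile grid (default 19; levels s/(k+1))
#' @param mode \code{"composite"} (shared coefficients across
#'   quantiles) or \code{"per_tau"}
#' @param minPrevalence,minNonzeroPerBatch see [filterOTUs()]
#' @param stochasticZeros see [correctNonsystematic()]
#' @param seed seed recorded in provenance and applied before any
#'   stochastic option
#' @return a \linkS4class{BatchCorrection}
#' @examples
#' cfg <- simConfig(nPerBatch = c(20, 20), m = 15, gamma = c(0.6, -0.6),
#'                  seed = 7)
#' sim <- simulateBatchExperiment(cfg)
#' res <- correctBatchEffects(sim$experiment, reference = "batch1")
#' res
#' @export
correctBatchEffects <- function(object, reference = "auto", alpha = 0.05,
                                k = 19L, mode = c("composite", "per_tau"),
                                minPrevalence = 0.1,
                                minNonzeroPerBatch = 3L,
                                stochasticZeros = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  object <- filterOTUs(object, minPrevalence, minNonzeroPerBatch)
  refReport <- NULL
  if (identical(reference, "auto")) {
    refReport <- selectReference(object, alpha)
    reference <- refReport@selected
  } else {
    stopifnot(reference %in% levels(batchLabels(object)))
  }
  referenceBatch(object) <- reference

  st1 <- correctSystematic(object)
  stage1 <- st1$experiment

  m1 <- counts(stage1)
  X <- covariateMatrix(stage1)
  b <- batchLabels(stage1)
  taus <- tauGrid(k)
  usable <- names(Filter(function(f) !f$uncorrectable, st1$fits))
  zeroFits <- list(); cqrFits <- list()
  for (otu in usable) {
    y <- m1[otu, ]
    zeroFits[[otu]] <- fitZeroOTU(y, X, b, refLevel = reference)
    cqrFits[[otu]] <- fitCQROTU(y[y > 0], X[y > 0, , drop = FALSE],
                                droplevels(b[y > 0]), taus, mode,
                                refLevel = reference)
  }
  corrected <- correctNonsystematic(stage1, zeroFits, cqrFits,
                                    reference, stochasticZeros)
  methods::new("BatchCorrection",
               corrected = corrected, stage1 = stage1, input = object,
               nbFits = st1$fits, zeroFits = zeroFits,
               cqrFits = cqrFits, referenceReport = refReport,
               provenance = list(reference = reference, alpha = alpha,
                                 k = as.integer(k), mode = mode,
                                 minPrevalence = minPrevalence,
                                 minNonzeroPerBatch = minNonzeroPerBatch,
                                 stochasticZeros = stochasticZeros,
                                 seed = seed))
}

#' Per-OTU stage-1 fit summary table
#'
#' @param object a \linkS4class{BatchCorrection}
#' @return data.frame with one row per fitted OTU: sigma, per-batch
#'   gamma and theta, theta*, convergence flags
#' @export
nbFitSummary <- function(object) {
  stopifnot(methods::is(object, "BatchCorrection"))
  fits <- object@nbFits
  if (!length(fits)) return(data.frame())
  lv <- names(fits[[1]]$gamma)
  do.call(rbind, lapply(names(fits), function(otu) {
    f <- fits[[otu]]
    row <- data.frame(otu = otu, sigma = f$sigma,
                      thetaStar = f$thetaStar,
                      converged = f$converged,
                      uncorrectable = f$uncorrectable)
    for (g in lv) {
      row[[paste0("gamma.", g)]] <- f$gamma[[g]]
      row[[paste0("theta.", g)]] <- f$theta[[g]]
    }
    row
  }))
}

#' Resolve a pipeline run configuration
#'
#' Merges a YAML config file (if given) with directly supplied
#' arguments; arguments win. See [runPipeline()] for the recognised
#' keys.
#'
#' @param configFile path to a YAML file, or NULL
#' @param ... key = value overrides
#' @return list of class \code{runConfig}
#' @export
runConfig <- function(configFile = NULL, ...) {
  cfg <- list(countPath = NULL, metadataPath = NULL,
              batchColumn = "batch", covariateColumns = character(0),
              orientation = "samples_by_otus", sampleColumn = NULL,
              reference = "auto", alpha = 0.05, k = 19L,
              mode = "composite", minPrevalence = 0.1,
              minNonzeroPerBatch = 3L, stochasticZeros = FALSE,
              metrics = .METRICS, nPerm = 999L, pseudocount = 0.5,
              seed = 1L, outDir = ".")
  if (!is.null(configFile)) {
    fromFile <- yaml::read_yaml(configFile)
    unknown <- setdiff(names(fromFile), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(fromFile)] <- fromFile
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg$covariateColumns <- as.character(cfg$covariateColumns)
  structure(cfg, class = "runConfig")
}

#' Run the whole pipeline from files to files
#'
#' Reads a count table and metadata, runs [correctBatchEffects()] and
#' [evaluateCorrection()], and writes to \code{outDir}: the corrected
#' table (\code{corrected.tsv}) and stage-1 table
#' (\code{stage1.tsv}), the stage-1 fit summary
#' (\code{nb_fits.tsv}), the evaluation summary
#' (\code{evaluation.tsv}), per-metric PCoA coordinates, and a
#' provenance JSON echoing the resolved configuration and seed.
#'
#' @param config a [runConfig()] (or a YAML path accepted by it)
#' @return invisibly, a list with the \linkS4class{BatchCorrection}
#'   and the evaluation report
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- runConfig(config)
  stopifnot(inherits(config, "runConfig"))
  if (is.null(config$countPath) || is.null(config$metadataPath))
    stop("countPath and metadataPath are required")
  expt <- readBatchCountExperiment(
    config$countPath, config$metadataPath, config$batchColumn,
    config$covariateColumns, config$orientation, config$sampleColumn)
  res <- correctBatchEffects(
    expt, reference = config$reference, alpha = config$alpha,
    k = config$k, mode = config$mode,
    minPrevalence = config$minPrevalence,
    minNonzeroPerBatch = config$minNonzeroPerBatch,
    stochasticZeros = config$stochasticZeros, seed = config$seed)
  ev <- evaluateCorrection(res@input, res@corrected,
                           metrics = config$metrics,
                           nPerm = config$nPerm, seed = config$seed,
                           pseudocount = config$pseudocount)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  writeCountTable(res@corrected, file.path(config$outDir, "corrected.tsv"))
  writeCountTable(res@stage1, file.path(config$outDir, "stage1.tsv"))
  utils::write.table(nbFitSummary(res),
                     file.path(config$outDir, "nb_fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ev$summary,
                     file.path(config$outDir, "evaluation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (met in names(ev$pcoa$after))
    utils::write.table(ev$pcoa$after[[met]],
                       file.path(config$outDir,
                                 paste0("pcoa_", met, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- c(unclass(config),
            list(selectedReference = res@provenance$reference))
  prov$metrics <- as.list(prov$metrics)
  jsonlite::write_json(prov,
                       file.path(config$outDir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(correction = res, evaluation = ev))
}
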