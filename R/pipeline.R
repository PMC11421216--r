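# End-to-end driver: curate -> split -> embed -> model-select -> fit ->
# predict -> evaluate, persisting every intermediate under a run directory.

.readConfigFile <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.asGrid <- function(cfg, seed) {
  if (is.null(cfg)) return(defaultGrid(seed = seed))
  if (is(cfg, "RegressorSpec")) return(list(cfg))
  if (is.list(cfg) && all(vapply(cfg, is, TRUE, "RegressorSpec"))) return(cfg)
  # list of plain lists: [{family: knn, nNeighbors: 3}, ...]
  lapply(cfg, function(entry) {
    entry <- as.list(entry)
    fam <- entry$family %||% stop("grid entry without a family")
    entry$family <- NULL
    do.call(regressorSpec, c(list(family = fam), entry, list(seed = seed)))
  })
}

#' Run the full prediction pipeline
#'
#' Executes the standard protocol on one configuration: read (or simulate)
#' sequences and measurements, curate labels, split train/validation, embed,
#' grid-search a regressor on the training side, fit and predict, and
#' produce a delta-filtered evaluation report. Every intermediate artifact
#' is written under \code{outputDir} (curated labels, split file, embedding
#' cache, model file, predictions, report, manifest), and per-stage counts
#' are logged via \code{message()}.
#'
#' @param config named list (or path to a YAML/JSON file) with entries:
#'   \describe{
#'     \item{simulate}{logical; if \code{TRUE}, inputs come from
#'       \code{\link{simulateDataset}} under \code{config$simulation}
#'       (a list of \code{\link{simulationConfig}} arguments).}
#'     \item{fasta, measurements}{input paths (when not simulating).}
#'     \item{annotations}{optional named paths: pfam, ec, superkingdom.}
#'     \item{split}{list: \code{strategy} ("random" or "homology"),
#'       \code{validationFraction}, \code{eps}, \code{minSamples}.}
#'     \item{embedder}{"onehot" (default) or a list
#'       \code{list(name = "import", path = ...)}.}
#'     \item{regressor}{NULL for the default grid, or a list of spec
#'       entries, e.g. \code{list(list(family = "knn", nNeighbors = 5))}.}
#'     \item{evaluation}{list: \code{deltas}, \code{groupColumn}
#'       (e.g. "superkingdom").}
#'     \item{seed}{integer; one pipeline-level seed drives every
#'       stochastic stage.}
#'   }
#' @param outputDir run directory (created if needed).
#' @return the \linkS4class{EvalReport}, invisibly; all artifacts on disk.
#' @export
runPipeline <- function(config, outputDir) {
  if (is.character(config)) config <- .readConfigFile(config)
  seed <- as.integer(config$seed %||% 1L)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed)

  # -- inputs -----------------------------------------------------------
  if (isTRUE(config$simulate)) {
    simCfg <- do.call(simulationConfig,
                      c(as.list(config$simulation %||% list()),
                        if (is.null(config$simulation$seed))
                          list(seed = seed)))
    sim <- simulateDataset(simCfg)
    records <- sim$records
    measurements <- sim$measurements
    writeSimulatedDataset(sim, file.path(outputDir, "simulated"))
    manifest$simulated <- TRUE
  } else {
    if (is.null(config$fasta) || !file.exists(config$fasta))
      stop("input FASTA not found: ", config$fasta %||% "<missing>")
    if (is.null(config$measurements) || !file.exists(config$measurements))
      stop("measurement table not found: ",
           config$measurements %||% "<missing>")
    records <- readFastaProteins(config$fasta)
    measurements <- readMeasurementTable(config$measurements)
    for (col in c("pfam", "ec", "superkingdom")) {
      path <- config$annotations[[col]]
      if (!is.null(path)) {
        ann <- readAnnotationTable(path, col)
        joined <- vapply(ann, paste, "", collapse = ";")
        mc <- S4Vectors::mcols(records)
        if (is.null(mc)) mc <- S4Vectors::DataFrame(row.names = names(records))
        mc[[col]] <- unname(joined[names(records)])
        S4Vectors::mcols(records) <- mc
      }
    }
  }
  message(sprintf("[input] %d sequences, %d measurement rows",
                  length(records), nrow(measurements)))

  # -- curation ---------------------------------------------------------
  dataset <- curateOptimalPh(measurements, records)
  message(sprintf("[curate] %d labelled records (%d discarded by std filter)",
                  length(dataset), length(attr(dataset, "discarded"))))
  writeLabelTable(dataset, file.path(outputDir, "curated_labels.tsv"))
  manifest$nCurated <- length(dataset)
  manifest$nDiscarded <- length(attr(dataset, "discarded"))

  # -- split ------------------------------------------------------------
  sp <- config$split %||% list()
  strategy <- sp$strategy %||% "random"
  frac <- sp$validationFraction %||% 0.25
  split <- switch(strategy,
    random = randomSplit(dataset, validationFraction = frac, seed = seed),
    homology = {
      s <- homologySplit(dataset, eps = sp$eps %||% 0.4,
                         minSamples = sp$minSamples %||% 1L,
                         validationFraction = frac, seed = seed)
      cl <- attr(s, "clusters")
      orphans <- if (is.na(orphanCluster(cl))) 0L
                 else sum(clusterIndices(cl) == orphanCluster(cl))
      message(sprintf("[split] %d clusters, %d orphan sequences",
                      max(clusterIndices(cl)), orphans))
      s
    },
    stop("runPipeline supports the 'random' and 'homology' strategies; ",
         "use ecSplit()/pfamHoldoutSplits() for fold-structured protocols"))
  message(sprintf("[split] %s: %d train / %d validation", strategy,
                  length(trainIds(split)), length(validationIds(split))))
  writeSplitAssignment(split, file.path(outputDir, "split.tsv"))
  manifest$split <- list(strategy = strategy, nTrain = length(trainIds(split)),
                         nValidation = length(validationIds(split)))

  # -- embeddings -------------------------------------------------------
  emb <- config$embedder %||% "onehot"
  if (is.character(emb)) emb <- list(name = emb)
  spec <- if (identical(emb$name, "onehot")) {
    onehotEmbedder()
  } else if (identical(emb$name, "import")) {
    importEmbedder(emb$path, name = emb$label %||% "imported")
  } else stop("unknown embedder: ", emb$name %||% "<unnamed>")
  X <- embedDataset(dataset, spec,
                    cachePath = file.path(outputDir, "embeddings.tsv"))
  nTrunc <- attr(truncateSequence(sequences(dataset), spec@maxLength),
                 "nTruncated")
  message(sprintf("[embed] %s: %d x %d (%d sequences truncated)",
                  spec@name, nrow(X), ncol(X), nTrunc))

  # -- model selection and fit -----------------------------------------
  y <- phLabels(dataset)
  trX <- X[trainIds(split), , drop = FALSE]
  attr(trX, "embedder") <- spec@name
  vaX <- X[validationIds(split), , drop = FALSE]
  attr(vaX, "embedder") <- spec@name
  trY <- y[trainIds(split)]
  grid <- .asGrid(config$regressor, seed)
  gs <- gridSearch(grid, trX, trY, nFolds = min(5L, length(trY)),
                   seed = seed)
  message(sprintf("[train] grid search over %d specs; best %s (cv MAE %.3f)",
                  length(grid), .specLabel(gs$best), gs$bestScore))
  utils::write.table(gs$table, file.path(outputDir, "grid_search.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  model <- fitRegressor(gs$best, trX, trY)
  writePhModel(model, file.path(outputDir, "model.rds"))

  # -- predict and evaluate --------------------------------------------
  pred <- predict(model, vaX)
  predDf <- data.frame(id = validationIds(split),
                       ph_true = unname(y[validationIds(split)]),
                       ph_pred = unname(pred))
  predDf <- predDf[order(predDf$id), ]
  utils::write.table(predDf, file.path(outputDir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- config$evaluation %||% list()
  groups <- NULL
  if (!is.null(ev$groupColumn)) {
    ann <- datasetAnnotations(dataset, ev$groupColumn)
    if (!is.null(ann))
      groups <- vapply(ann[validationIds(split)], paste, "", collapse = ";")
  }
  report <- evaluatePredictions(
    y[validationIds(split)], pred, trainMedian = median(unname(trY)),
    deltas = ev$deltas %||% c(0, 0.5, 1, 1.5), groups = groups)
  writeEvalReport(report, file.path(outputDir, "report.tsv"))
  manifest$mae <- report@mae
  manifest$spearman <- report@spearman
  manifest$bestSpec <- .specLabel(gs$best)
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  message(sprintf("[evaluate] n = %d, MAE %.3f, Spearman %s", report@n,
                  report@mae,
                  if (is.na(report@spearman)) "NA"
                  else sprintf("%.3f", report@spearman)))
  invisible(report)
}

#' Write an evaluation report as delimited text
#'
#' Three sections separated by comment lines: overall metrics, the delta
#' table and (when present) the group table.
#'
#' @param report an \linkS4class{EvalReport}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#overall n=%d mae=%.17g spearman=%s center=%.17g",
                     report@n, report@mae,
                     if (is.na(report@spearman)) "NA"
                     else sprintf("%.17g", report@spearman),
                     report@center), con)
  writeLines("#delta_table", con)
  utils::write.table(report@deltaTable, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(report@groupTable)) {
    writeLines("#group_table", con)
    utils::write.table(report@groupTable, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Audit a run directory for split leakage
#'
#' Re-reads the persisted split and predictions of a pipeline run and
#' verifies that no validation id leaked into any artifact consumed by
#' model fitting.
#'
#' @param outputDir a directory written by \code{\link{runPipeline}}.
#' @return \code{TRUE} invisibly; stops with a message on any violation.
#' @export
auditRun <- function(outputDir) {
  split <- readSplitAssignment(file.path(outputDir, "split.tsv"))
  val <- validationIds(split)
  if (length(intersect(val, trainIds(split))))
    stop("audit: train/validation overlap in split file")
  model <- readPhModel(file.path(outputDir, "model.rds"))
  leaked <- intersect(val, model@trainIds)
  if (length(leaked))
    stop("audit: validation ids used for fitting: ",
         paste(leaked, collapse = ", "))
  invisible(TRUE)
}
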