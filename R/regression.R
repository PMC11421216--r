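# Regressors on embeddings: k-nearest-neighbour, gradient-boosted trees
# (xgboost) and the naive training-median constant, plus grid-search model
# selection by cross-validated MAE.

#' Build a regressor specification
#'
#' @param family \code{"knn"}, \code{"gbt"} or \code{"naive_median"}.
#' @param ... family hyperparameters. knn: \code{nNeighbors} (default 5),
#'   \code{weights} (\code{"uniform"} or \code{"distance"}). gbt:
#'   \code{maxDepth} (default 6), \code{nTrees} (default 100),
#'   \code{learningRate} (default 0.1). naive_median: none.
#' @param seed integer seed used by stochastic fitters.
#' @return a \linkS4class{RegressorSpec}.
#' @examples
#' regressorSpec("knn", nNeighbors = 3, weights = "uniform")
#' @export
regressorSpec <- function(family = c("knn", "gbt", "naive_median"), ...,
                          seed = 1L) {
  family <- match.arg(family)
  new("RegressorSpec", family = family, params = list(...),
      seed = as.integer(seed))
}

#' Default hyperparameter grid
#'
#' The model-selection grid used when none is supplied: KNN over
#' \code{nNeighbors} in {1, 3, 5, 10, 20} x {uniform, distance} weights and
#' gradient boosting over depth {3, 6} x trees {100, 300} x learning rate
#' {0.05, 0.1}; fully overridable by passing any list of
#' \linkS4class{RegressorSpec}s to \code{\link{gridSearch}}.
#'
#' @param families subset of \code{c("knn", "gbt")} to include.
#' @param seed seed stored in every spec.
#' @return list of \linkS4class{RegressorSpec}s.
#' @export
defaultGrid <- function(families = c("knn", "gbt"), seed = 1L) {
  grid <- list()
  if ("knn" %in% families)
    for (k in c(1L, 3L, 5L, 10L, 20L))
      for (w in c("uniform", "distance"))
        grid <- c(grid, regressorSpec("knn", nNeighbors = k, weights = w,
                                      seed = seed))
  if ("gbt" %in% families)
    for (depth in c(3L, 6L))
      for (trees in c(100L, 300L))
        for (lr in c(0.05, 0.1))
          grid <- c(grid, regressorSpec("gbt", maxDepth = depth,
                                        nTrees = trees, learningRate = lr,
                                        seed = seed))
  grid
}

#' Fit a pH regressor
#'
#' @param spec a \linkS4class{RegressorSpec}.
#' @param X numeric embedding matrix (rows = sequences, ids as rownames).
#' @param y numeric pH labels parallel to the rows of \code{X}.
#' @return a \linkS4class{PhModel}.
#' @export
fitRegressor <- function(spec, X, y) {
  if (!is(spec, "RegressorSpec")) stop("spec must be a RegressorSpec")
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (length(y) < 1L) stop("at least one training row is required")
  if (any(!is.finite(y))) stop("labels contain NA or non-finite values")
  p <- spec@params
  state <- switch(spec@family,
    naive_median = list(median = median(y)),
    knn = {
      k <- as.integer(p$nNeighbors %||% 5L)
      if (nrow(X) < k)
        stop(sprintf("knn needs at least nNeighbors = %d training rows", k))
      list(X = X, y = y, k = k, weights = p$weights %||% "uniform")
    },
    gbt = {
      booster <- xgboost::xgboost(
        x = X, y = y,
        max_depth = as.integer(p$maxDepth %||% 6L),
        learning_rate = p$learningRate %||% 0.1,
        nrounds = as.integer(p$nTrees %||% 100L),
        objective = "reg:squarederror",
        nthreads = 1L, verbosity = 0L, seed = spec@seed)
      list(booster = booster)
    })
  new("PhModel", spec = spec, state = state,
      trainIds = rownames(X) %||% as.character(seq_len(nrow(X))),
      embedderName = attr(X, "embedder") %||% "unknown",
      d = ncol(X))
}

.knnPredict <- function(state, X) {
  # squared Euclidean distances via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
  tr <- state$X
  d2 <- outer(rowSums(X^2), rowSums(tr^2), "+") - 2 * tcrossprod(X, tr)
  d2[d2 < 0] <- 0
  k <- state$k
  apply2 <- function(i) {
    di <- d2[i, ]
    nn <- order(di, seq_along(di))[seq_len(k)]  # ties broken by train order
    if (state$weights == "uniform") {
      mean(state$y[nn])
    } else {
      dn <- sqrt(di[nn])
      exact <- dn < 1e-12
      if (any(exact)) mean(state$y[nn][exact])
      else stats::weighted.mean(state$y[nn], 1 / dn)
    }
  }
  vapply(seq_len(nrow(X)), apply2, 0)
}

#' Predict optimal pH with a fitted model
#'
#' @param object a \linkS4class{PhModel}.
#' @param newdata embedding matrix with the model's dimension.
#' @param ... unused.
#' @return named numeric vector of pH predictions (one per row).
#' @export
setMethod("predict", "PhModel", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (nrow(X) == 0L) return(setNames(numeric(0), character(0)))
  if (ncol(X) != object@d)
    stop(sprintf("embedding dimension %d does not match model dimension %d",
                 ncol(X), object@d))
  emb <- attr(newdata, "embedder")
  if (!is.null(emb) && object@embedderName != "unknown" &&
      emb != object@embedderName)
    stop(sprintf("model was fitted on '%s' embeddings, got '%s'",
                 object@embedderName, emb))
  out <- switch(object@spec@family,
    naive_median = rep(object@state$median, nrow(X)),
    knn = .knnPredict(object@state, X),
    gbt = as.numeric(predict(object@state$booster, X)))
  setNames(out, rownames(X))
})

.specLabel <- function(spec) {
  p <- spec@params
  if (length(p) == 0L) return(spec@family)
  paste0(spec@family, "(",
         paste(names(p), vapply(p, function(z) paste(z, collapse = "/"), ""),
               sep = "=", collapse = ","), ")")
}

#' Grid search by cross-validated error
#'
#' Rows are partitioned into \code{nFolds} seeded folds; every candidate
#' specification is fitted on each fold complement and scored on the held
#' fold; candidates are ranked by mean validation MAE (or Spearman, where
#' larger is better). Ties go to the earlier grid entry.
#'
#' @param grid nonempty list of \linkS4class{RegressorSpec}s (see
#'   \code{\link{defaultGrid}}).
#' @param X embedding matrix.
#' @param y numeric labels.
#' @param nFolds number of cross-validation folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @param metric \code{"mae"} (default) or \code{"spearman"}.
#' @return list with \code{best} (the winning spec), \code{bestScore}, and
#'   \code{table} (data.frame: spec label, family, mean score per
#'   candidate, in grid order).
#' @export
gridSearch <- function(grid, X, y, nFolds = 5L, seed = 1L, metric = "mae") {
  if (!length(grid)) stop("grid must be nonempty")
  metric <- match.arg(metric, c("mae", "spearman"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  nFolds <- as.integer(nFolds)
  if (n < nFolds) stop("need at least as many rows as folds")
  fold <- withr::with_seed(as.integer(seed),
                           sample(rep_len(seq_len(nFolds), n)))
  scoreSpec <- function(spec) {
    perFold <- vapply(seq_len(nFolds), function(f) {
      tr <- fold != f
      tryCatch({
        model <- fitRegressor(spec, X[tr, , drop = FALSE], y[tr])
        pred <- predict(model, X[!tr, , drop = FALSE])
        if (metric == "mae") maeScore(y[!tr], pred)
        else spearmanScore(y[!tr], pred)
      }, error = function(e) NA_real_)  # infeasible spec (e.g. k > n) skipped
    }, 0)
    mean(perFold)
  }
  scores <- vapply(grid, scoreSpec, 0)
  if (all(is.na(scores))) stop("no grid entry could be fitted")
  ranked <- if (metric == "mae") scores else -scores
  ranked[is.na(ranked)] <- Inf
  best <- which.min(ranked)
  list(best = grid[[best]], bestScore = scores[best],
       table = data.frame(spec = vapply(grid, .specLabel, ""),
                          family = vapply(grid, function(s) s@family, ""),
                          score = scores))
}

#' Persist a fitted model to a single file
#'
#' @param model a \linkS4class{PhModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePhModel <- function(model, path) {
  if (model@spec@family == "gbt") {
    raw <- xgboost::xgb.save.raw(model@state$booster)
    model@state <- list(booster_raw = raw)
  }
  saveRDS(model, path)
  invisible(path)
}

#' Load a model written by \code{\link{writePhModel}}
#'
#' @param path file path.
#' @return a \linkS4class{PhModel}.
#' @export
readPhModel <- function(path) {
  model <- readRDS(path)
  if (model@spec@family == "gbt" && !is.null(model@state$booster_raw))
    model@state <- list(booster = xgboost::xgb.load.raw(model@state$booster_raw))
  model
}
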