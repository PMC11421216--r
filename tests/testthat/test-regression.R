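embMat <- function(X, ids = NULL) {
  X <- as.matrix(X)
  rownames(X) <- ids %||% sprintf("r%02d", seq_len(nrow(X)))
  attr(X, "embedder") <- "test"
  X
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the naive model stores and predicts the training median", {
  X <- embMat(matrix(rnorm(6), 3, 2))
  m <- fitRegressor(regressorSpec("naive_median"), X, c(5, 7, 9))
  expect_equal(m@state$median, 7)
  probe <- embMat(matrix(rnorm(10), 5, 2))
  expect_equal(unname(predict(m, probe)), rep(7, 5))
  # predictions are invariant to the features entirely
  expect_equal(unname(predict(m, probe * 100)), rep(7, 5))
  expect_equal(length(predict(m, probe[0, , drop = FALSE])), 0L)
})

test_that("KNN recovers planted neighbors", {
  X <- embMat(rbind(c(0, 0), c(1, 0), c(-1, 0), c(10, 10)))
  y <- c(6, 4, 8, 12)
  m1 <- fitRegressor(regressorSpec("knn", nNeighbors = 1), X, y)
  # nearest neighbor of a training row is itself
  expect_equal(unname(predict(m1, X)), y)
  # query at the origin with k = 2: its own point plus one equidistant pair
  m2 <- fitRegressor(regressorSpec("knn", nNeighbors = 2), X[2:4, ], y[2:4])
  probe <- embMat(matrix(c(0, 0), 1), "q")
  expect_equal(unname(predict(m2, probe)), (4 + 8) / 2)
  # uniform predictions stay within the training label range
  withr::with_seed(17, {
    Xr <- embMat(matrix(rnorm(60), 20, 3))
    yr <- runif(20, 3, 11)
    mk <- fitRegressor(regressorSpec("knn", nNeighbors = 5), Xr, yr)
    pr <- predict(mk, embMat(matrix(rnorm(30), 10, 3)))
    expect_true(all(pr >= min(yr) & pr <= max(yr)))
  })
  expect_error(fitRegressor(regressorSpec("knn", nNeighbors = 10),
                            X[1:2, ], y[1:2]), "nNeighbors")
  expect_error(fitRegressor(regressorSpec("knn"), X, c(1, NA, 2, 3)),
               "NA|finite")
})

test_that("distance weighting interpolates and honors exact matches", {
  X <- embMat(rbind(c(0, 0), c(3, 0)))
  y <- c(4, 8)
  m <- fitRegressor(regressorSpec("knn", nNeighbors = 2,
                                  weights = "distance"), X, y)
  # query at distance 1 and 2: weights 1 and 1/2 -> (4 + 0.5*8) / 1.5
  p <- predict(m, embMat(matrix(c(1, 0), 1)))
  expect_equal(unname(p), (4 + 0.5 * 8) / 1.5)
  # exact overlap with a training point returns that label
  expect_equal(unname(predict(m, embMat(matrix(c(3, 0), 1)))), 8)
})

test_that("gradient boosting is deterministic per seed and learns a signal", {
  withr::with_seed(23, {
    X <- embMat(matrix(runif(400), 100, 4))
    y <- 5 + 4 * X[, 1] + rnorm(100, 0, 0.1)
  })
  spec <- regressorSpec("gbt", maxDepth = 3, nTrees = 50,
                        learningRate = 0.1, seed = 9L)
  probe <- embMat(matrix(runif(40), 10, 4))
  p1 <- predict(fitRegressor(spec, X, y), probe)
  p2 <- predict(fitRegressor(spec, X, y), probe)
  expect_identical(p1, p2)
  expect_lt(maeScore(5 + 4 * probe[, 1], p1), 1.0)
})

test_that("model persistence round-trips through a single file", {
  X <- embMat(matrix(rnorm(40), 20, 2))
  y <- rnorm(20, 7)
  probe <- embMat(matrix(rnorm(10), 5, 2))
  for (spec in list(regressorSpec("knn", nNeighbors = 3),
                    regressorSpec("gbt", nTrees = 10),
                    regressorSpec("naive_median"))) {
    m <- fitRegressor(spec, X, y)
    f <- withr::local_tempfile(fileext = ".rds")
    writePhModel(m, f)
    expect_equal(predict(readPhModel(f), probe), predict(m, probe),
                 tolerance = 1e-9)
  }
})

test_that("dimension and embedder mismatches are rejected at predict time", {
  X <- embMat(matrix(rnorm(20), 10, 2))
  m <- fitRegressor(regressorSpec("knn", nNeighbors = 2), X, rnorm(10, 7))
  expect_error(predict(m, matrix(rnorm(30), 10, 3)), "dimension")
  wrong <- embMat(matrix(rnorm(20), 10, 2))
  attr(wrong, "embedder") <- "different"
  expect_error(predict(m, wrong), "embedding")
})

test_that("grid search ranks by cross-validated MAE", {
  # y depends only on feature 1 and the feature is noiseless: 1-NN is
  # Bayes-optimal while n-NN collapses toward the global mean
  withr::with_seed(29, {
    x1 <- runif(60, 0, 1)
    X <- embMat(cbind(x1, matrix(runif(120, 0, 0.01), 60, 2)))
    y <- 3 + 8 * x1
  })
  grid <- list(regressorSpec("knn", nNeighbors = 1),
               regressorSpec("knn", nNeighbors = 55))
  gs <- gridSearch(grid, X, y, nFolds = 5, seed = 4L)
  expect_equal(gs$best@params$nNeighbors, 1)
  expect_equal(gs$bestScore, min(gs$table$score, na.rm = TRUE))
  # determinism per seed
  gs2 <- gridSearch(grid, X, y, nFolds = 5, seed = 4L)
  expect_identical(gs$table, gs2$table)
  # singleton grid returns its only member
  one <- gridSearch(list(regressorSpec("naive_median")), X, y, seed = 1L)
  expect_identical(one$best@family, "naive_median")
  expect_error(gridSearch(list(), X, y), "nonempty")
})
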