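mkD <- function(m, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("x%d", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  m
}

test_that("density clustering handles the canonical small cases", {
  # two mutual neighbors form one cluster
  D <- mkD(matrix(c(0, 0.1, 0.1, 0), 2))
  cl <- densityCluster(D, eps = 0.2, minSamples = 1L)
  expect_equal(unname(clusterIndices(cl)), c(1L, 1L))
  expect_true(is.na(orphanCluster(cl)))

  # chain A-B-C is density-connected even though A-C exceeds eps
  D <- mkD(matrix(c(0, 0.1, 0.3,
                    0.1, 0, 0.1,
                    0.3, 0.1, 0), 3), c("A", "B", "C"))
  cl <- densityCluster(D, eps = 0.12, minSamples = 1L)
  expect_equal(unname(clusterIndices(cl)), c(1L, 1L, 1L))

  # two mutually distant points under minSamples 2: both noise -> orphan
  D <- mkD(matrix(c(0, 0.9, 0.9, 0), 2))
  cl <- densityCluster(D, eps = 0.2, minSamples = 2L)
  expect_equal(orphanCluster(cl), 1L)
  expect_equal(unname(clusterIndices(cl)), c(1L, 1L))

  expect_error(densityCluster(D, eps = 0), "eps")
})

test_that("border points join clusters deterministically, noise is orphaned", {
  # x1,x2,x3 dense core region; x4 border of x1; x5 far from everything
  D <- mkD(matrix(0.9, 5, 5))
  diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0.05
  D[1, 3] <- D[3, 1] <- 0.05
  D[2, 3] <- D[3, 2] <- 0.05
  D[1, 4] <- D[4, 1] <- 0.08
  cl <- densityCluster(D, eps = 0.1, minSamples = 3L)
  idx <- clusterIndices(cl)
  expect_equal(unname(idx[c("x1", "x2", "x3", "x4")]), rep(1L, 4))
  expect_equal(unname(idx["x5"]), orphanCluster(cl))
  expect_equal(orphanCluster(cl), 2L)
})

test_that("minSamples = 1 clustering equals eps-graph connected components", {
  for (seed in 1:20) {
    n <- withr::with_seed(seed, sample(5:50, 1))
    D <- randomDistanceMatrix(n, seed = seed + 100)
    eps <- withr::with_seed(seed + 200, runif(1, 0.05, 0.6))
    got <- unname(clusterIndices(densityCluster(D, eps, minSamples = 1L)))
    want <- unionFindComponents(D, eps)
    # identical partitions up to relabeling: same co-membership relation
    expect_identical(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("raising eps never increases the component count (minSamples 1)", {
  D <- randomDistanceMatrix(30, seed = 42)
  counts <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), function(eps)
    max(clusterIndices(densityCluster(D, eps, minSamples = 1L))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster packing keeps clusters whole and near the 3:1 target", {
  # four singleton clusters: exactly one validation id
  cl <- new("ClusterAssignment",
            clusters = setNames(1:4, c("a", "b", "c", "d")),
            orphanCluster = NA_integer_)
  sp <- clustersToSplit(cl, validationFraction = 0.25, seed = 3L)
  expect_length(validationIds(sp), 1L)
  expect_length(trainIds(sp), 3L)

  # {3 ids} + {1 id}: the singleton must sit alone on one side
  cl <- new("ClusterAssignment",
            clusters = setNames(c(1L, 1L, 1L, 2L), c("a", "b", "c", "d")),
            orphanCluster = NA_integer_)
  for (seed in 1:5) {
    sp <- clustersToSplit(cl, validationFraction = 0.25, seed = seed)
    sides <- list(trainIds(sp), validationIds(sp))
    expect_true(any(vapply(sides, function(s) identical(s, "d"), TRUE)))
    expect_length(intersect(trainIds(sp), validationIds(sp)), 0L)
    expect_setequal(c(trainIds(sp), validationIds(sp)), c("a", "b", "c", "d"))
  }

  # a single all-covering cluster cannot be split
  cl <- new("ClusterAssignment", clusters = setNames(c(1L, 1L), c("a", "b")),
            orphanCluster = NA_integer_)
  expect_error(clustersToSplit(cl), "single cluster")
})

test_that("homology split separates train and validation by more than eps", {
  sim <- smallSimulation(seed = 21L)
  ds <- curateOptimalPh(sim$measurements, sim$records)
  S <- pairwiseSimilarity(ds)
  D <- similarityToDistance(S)
  sp <- homologySplit(ds, eps = 0.4, minSamples = 1L, seed = 2L, S = S)
  cross <- D[trainIds(sp), validationIds(sp), drop = FALSE]
  expect_true(all(cross > 0.4))
  # members of one planted family never straddle the split
  fam <- setNames(sim$truth$family, sim$truth$id)
  expect_length(intersect(fam[trainIds(sp)], fam[validationIds(sp)]), 0L)
})
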