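# Density clustering on a precomputed distance matrix and the packing of
# whole clusters into train/validation sides. Keeping similar sequences on
# one side is what prevents homology leakage.

#' Cluster assignment container
#'
#' @slot clusters named integer vector mapping id to a 1-based cluster
#'   index (contiguous).
#' @slot orphanCluster integer index of the cluster that collects all noise
#'   points, or \code{NA} when there was no noise.
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(clusters = "integer", orphanCluster = "integer"))

setValidity("ClusterAssignment", function(object) {
  cl <- object@clusters
  if (is.null(names(cl)) || anyDuplicated(names(cl)))
    return("every id must be assigned exactly one cluster")
  if (length(cl) && !identical(sort(unique(unname(cl))), seq_len(max(cl))))
    return("cluster indices must be contiguous from 1")
  TRUE
})

#' @rdname ClusterAssignment-class
#' @param x a \linkS4class{ClusterAssignment}.
#' @export
clusterIndices <- function(x) x@clusters

#' @rdname ClusterAssignment-class
#' @export
orphanCluster <- function(x) x@orphanCluster

setMethod("show", "ClusterAssignment", function(object) {
  k <- if (length(object@clusters)) max(object@clusters) else 0L
  cat(sprintf("ClusterAssignment: %d ids in %d clusters",
              length(object@clusters), k))
  if (!is.na(object@orphanCluster))
    cat(sprintf(" (orphan cluster %d: %d ids)", object@orphanCluster,
                sum(object@clusters == object@orphanCluster)))
  cat("\n")
})

#' Density clustering (DBSCAN) on a distance matrix
#'
#' Standard DBSCAN over a precomputed distance matrix: a point is a core
#' point when at least \code{minSamples} points (itself included) lie within
#' \code{eps}; clusters are the maximal density-connected sets grown from
#' core points, visited in id order so the result is deterministic; border
#' points join the first cluster that reaches them. All remaining noise
#' points are merged into a single orphan cluster (appended last), so every
#' id is assigned.
#'
#' With \code{minSamples = 1} every point is core and the clusters are
#' exactly the connected components of the graph with edges
#' \code{D[a, b] <= eps}; only in that regime is the cross-side distance
#' guarantee of the homology split strict.
#'
#' @param D symmetric distance matrix with zero diagonal (see
#'   \code{\link{similarityToDistance}}).
#' @param eps neighborhood radius in distance units, in (0, 1).
#' @param minSamples core-point threshold (neighbors within eps, self
#'   included); default 5.
#' @return a \linkS4class{ClusterAssignment}.
#' @export
densityCluster <- function(D, eps, minSamples = 5L) {
  .checkSquare(D, "distance matrix")
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 1)
    stop("eps must lie in (0, 1)")
  minSamples <- as.integer(minSamples)
  if (minSamples < 1L) stop("minSamples must be >= 1")
  n <- nrow(D)
  ids <- rownames(D)
  neighbors <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(neighbors) >= minSamples
  labels <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(labels[i])) next
    k <- k + 1L
    labels[i] <- k
    queue <- neighbors[[i]]
    while (length(queue)) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (is.na(labels[j])) {
        labels[j] <- k
        if (core[j])
          queue <- c(queue, neighbors[[j]][is.na(labels[neighbors[[j]]])])
      }
    }
  }
  orphan <- NA_integer_
  if (anyNA(labels)) {
    orphan <- k + 1L
    labels[is.na(labels)] <- orphan
  }
  new("ClusterAssignment", clusters = setNames(labels, ids),
      orphanCluster = orphan)
}

#' Pack whole clusters into a train/validation split
#'
#' Clusters are shuffled by the seed and assigned whole to the validation
#' side until it reaches the target fraction of ids; the remainder forms the
#' training side. Because clusters are indivisible the achieved fraction can
#' deviate from the target by up to the largest assigned cluster. A cluster
#' whose addition would leave the training side empty is skipped. The orphan
#' cluster participates as one ordinary (possibly very large) cluster.
#'
#' @param clusters a \linkS4class{ClusterAssignment} covering the dataset.
#' @param validationFraction target share of ids on the validation side
#'   (default 0.25, i.e. a 3:1 train:validation ratio).
#' @param seed integer seed for the cluster shuffle.
#' @return a \linkS4class{SplitAssignment}.
#' @export
clustersToSplit <- function(clusters, validationFraction = 0.25, seed = 1L) {
  if (validationFraction <= 0 || validationFraction >= 1)
    stop("validationFraction must lie in (0, 1)")
  cl <- clusterIndices(clusters)
  n <- length(cl)
  k <- max(cl)
  if (k < 2L)
    stop("a single cluster covers the whole dataset; no valid split exists")
  target <- round(n * validationFraction)
  order <- withr::with_seed(as.integer(seed), sample.int(k))
  byCluster <- split(names(cl), unname(cl))
  val <- character()
  for (ci in order) {
    if (length(val) >= target) break
    members <- byCluster[[as.character(ci)]]
    if (length(val) + length(members) >= n) next  # would empty the train side
    val <- c(val, members)
  }
  splitAssignment(train = setdiff(names(cl), val), validation = val,
                  strategy = "homology")
}

#' Homology-based train/validation split
#'
#' Convenience wrapper chaining \code{\link{pairwiseSimilarity}},
#' \code{\link{similarityToDistance}}, \code{\link{densityCluster}} and
#' \code{\link{clustersToSplit}}.
#'
#' @param dataset a \linkS4class{CuratedDataset}.
#' @param eps DBSCAN neighborhood radius on identity distance.
#' @param minSamples DBSCAN core threshold.
#' @param validationFraction target validation share.
#' @param seed integer seed for cluster packing.
#' @param S optional precomputed similarity matrix (ids must cover the
#'   dataset); when missing the built-in aligner is used.
#' @return a \linkS4class{SplitAssignment} with the
#'   \linkS4class{ClusterAssignment} attached as \code{attr(x, "clusters")}.
#' @export
homologySplit <- function(dataset, eps = 0.4, minSamples = 5L,
                          validationFraction = 0.25, seed = 1L, S = NULL) {
  if (is.null(S)) S <- pairwiseSimilarity(dataset)
  ids <- datasetIds(dataset)
  if (!all(ids %in% rownames(S)))
    stop("similarity matrix does not cover all dataset ids")
  D <- similarityToDistance(S[ids, ids, drop = FALSE])
  cl <- densityCluster(D, eps = eps, minSamples = minSamples)
  split <- clustersToSplit(cl, validationFraction = validationFraction,
                           seed = seed)
  attr(split, "clusters") <- cl
  split
}
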