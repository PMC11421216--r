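#' Labelled protein dataset
#'
#' Holds protein sequences together with one curated optimal-pH label per
#' sequence. Sequences are a \linkS4class{AAStringSet}; optional annotations
#' (PFAM accessions, EC numbers, superkingdom) live in its \code{mcols} as
#' \code{";"}-joined character columns named \code{pfam}, \code{ec} and
#' \code{superkingdom}.
#'
#' @slot sequences \code{AAStringSet}, named by protein id.
#' @slot labels numeric vector of pH labels, parallel to \code{sequences}.
#'
#' @seealso \code{\link{curateOptimalPh}}, \code{\link{curatedDataset}}
#' @exportClass CuratedDataset
setClass("CuratedDataset",
  representation(sequences = "AAStringSet", labels = "numeric"))

setValidity("CuratedDataset", function(object) {
  ids <- names(object@sequences)
  msg <- character()
  if (is.null(ids) || any(!nzchar(ids)))
    msg <- c(msg, "all sequences must have nonempty ids")
  if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate ids: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@labels) != length(object@sequences))
    msg <- c(msg, "labels and sequences must have equal length")
  if (any(!is.finite(object@labels)) ||
      any(object@labels < 0 | object@labels > 14))
    msg <- c(msg, "labels must be finite pH values in [0, 14]")
  if (any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "sequences must be nonempty")
  if (length(msg)) msg else TRUE
})

#' Train/validation split assignment
#'
#' A partition of dataset ids into a training and a validation side, with an
#' optional fold structure (used by the EC-class split, where the validation
#' ids are additionally partitioned into cross-validation folds) and a set of
#' explicitly discarded ids.
#'
#' @slot train character vector of training ids.
#' @slot validation character vector of validation ids.
#' @slot folds list of character vectors partitioning \code{validation}
#'   (may be empty).
#' @slot discarded character vector of ids removed from both sides.
#' @slot strategy character scalar naming how the split was made.
#'
#' @exportClass SplitAssignment
setClass("SplitAssignment",
  representation(train = "character", validation = "character",
                 folds = "list", discarded = "character",
                 strategy = "character"),
  prototype(folds = list(), discarded = character(), strategy = "manual"))

setValidity("SplitAssignment", function(object) {
  msg <- character()
  if (length(intersect(object@train, object@validation)))
    msg <- c(msg, "train and validation ids overlap")
  if (length(intersect(object@discarded,
                       c(object@train, object@validation))))
    msg <- c(msg, "discarded ids overlap an assigned side")
  if (length(object@folds)) {
    fl <- unlist(object@folds, use.names = FALSE)
    if (anyDuplicated(fl) || !setequal(fl, object@validation))
      msg <- c(msg, "folds must partition the validation ids")
  }
  if (length(msg)) msg else TRUE
})

#' k-mer pH summary table
#'
#' The fitted state of the k-mer baseline predictor: for every k-mer observed
#' in the training sequences, the mean, minimum and maximum of the training
#' labels it co-occurred with, plus its occurrence count. The training-label
#' median is stored as the fallback prediction for query sequences sharing no
#' k-mer with the table.
#'
#' @slot k integer k-mer length.
#' @slot entries data.frame with columns \code{kmer}, \code{mean},
#'   \code{min}, \code{max}, \code{count}.
#' @slot trainMedian numeric, median of the training labels.
#' @slot skipped integer, number of training sequences shorter than k.
#' @slot multiset logical; if \code{TRUE} every k-mer occurrence in a
#'   training sequence contributed one copy of that sequence's label,
#'   otherwise one copy per distinct k-mer per sequence.
#'
#' @seealso \code{\link{buildKmerTable}}, \code{\link{predictKmerPh}}
#' @exportClass KmerTable
setClass("KmerTable",
  representation(k = "integer", entries = "data.frame",
                 trainMedian = "numeric", skipped = "integer",
                 multiset = "logical"))

setValidity("KmerTable", function(object) {
  msg <- character()
  e <- object@entries
  need <- c("kmer", "mean", "min", "max", "count")
  if (!all(need %in% names(e)))
    return(sprintf("entries must have columns %s", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (any(nchar(e$kmer) != object@k))
      msg <- c(msg, "all k-mer keys must have length k")
    if (any(e$min - e$mean > 1e-9 | e$mean - e$max > 1e-9))
      msg <- c(msg, "per entry min <= mean <= max must hold")
    if (any(e$count < 1L))
      msg <- c(msg, "counts must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted pH regressor
#'
#' Wraps one fitted regression model (k-nearest-neighbour, gradient-boosted
#' trees via xgboost, or the naive training-median constant) together with
#' the specification it was fitted under and the embedding it expects.
#'
#' @slot spec \linkS4class{RegressorSpec} used for fitting.
#' @slot state list of fitted state (opaque; family-specific).
#' @slot trainIds character ids of the training rows.
#' @slot embedderName character, name of the embedder that produced the
#'   training matrix.
#' @slot d integer embedding dimension the model accepts.
#'
#' @exportClass PhModel
setClass("PhModel",
  representation(spec = "ANY", state = "list", trainIds = "character",
                 embedderName = "character", d = "integer"))

#' Regressor specification
#'
#' @slot family one of \code{"knn"}, \code{"gbt"}, \code{"naive_median"}.
#' @slot params named list of hyperparameters for the family.
#' @slot seed integer seed for stochastic fitting.
#'
#' @seealso \code{\link{regressorSpec}}
#' @exportClass RegressorSpec
setClass("RegressorSpec",
  representation(family = "character", params = "list", seed = "integer"))

setValidity("RegressorSpec", function(object) {
  fam <- object@family
  if (length(fam) != 1L || !fam %in% c("knn", "gbt", "naive_median"))
    return("family must be one of knn, gbt, naive_median")
  p <- object@params
  if (fam == "knn") {
    k <- p$nNeighbors %||% 5L
    if (!is.numeric(k) || k < 1) return("knn requires nNeighbors >= 1")
    w <- p$weights %||% "uniform"
    if (!w %in% c("uniform", "distance"))
      return("knn weights must be uniform or distance")
  }
  if (fam == "gbt") {
    if (!is.null(p$learningRate) && (p$learningRate <= 0 || p$learningRate > 1))
      return("gbt learningRate must be in (0, 1]")
    if (!is.null(p$nTrees) && p$nTrees < 1) return("gbt nTrees must be >= 1")
  }
  TRUE
})

#' Evaluation report
#'
#' Metrics of a prediction set: overall mean absolute error and Spearman rank
#' correlation, the same metrics recomputed after delta-vicinity filtering
#' (test points whose true label lies within delta pH units of the filter
#' center — by convention the training-label median — are removed), and
#' optional per-group stratified metrics.
#'
#' @slot n integer, number of evaluated points.
#' @slot mae numeric, overall mean absolute error.
#' @slot spearman numeric, overall Spearman correlation (\code{NA} when
#'   either vector is constant, e.g. for the naive median predictor).
#' @slot center numeric, filter center used for the delta protocol.
#' @slot deltaTable data.frame with columns \code{delta}, \code{nKept},
#'   \code{mae}, \code{spearman}.
#' @slot groupTable data.frame with columns \code{group}, \code{n},
#'   \code{mae}, \code{spearman} (zero rows when no groups were supplied).
#'
#' @seealso \code{\link{evaluatePredictions}}
#' @exportClass EvalReport
setClass("EvalReport",
  representation(n = "integer", mae = "numeric", spearman = "numeric",
                 center = "numeric", deltaTable = "data.frame",
                 groupTable = "data.frame"))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (object@mae < 0) msg <- c(msg, "mae must be >= 0")
  if (!is.na(object@spearman) &&
      (object@spearman < -1 || object@spearman > 1))
    msg <- c(msg, "spearman must be in [-1, 1]")
  dt <- object@deltaTable
  if (nrow(dt) > 1L && is.unsorted(-dt$nKept[order(dt$delta)]))
    msg <- c(msg, "nKept must be non-increasing in delta")
  if (length(msg)) msg else TRUE
})

#' Sequence embedder specification
#'
#' The uniform adapter contract for turning sequences into fixed-length
#' vectors. The built-in averaged one-hot encoder satisfies it; adapters for
#' external language models or precomputed embedding tables plug in through
#' the same interface.
#'
#' @slot name character, embedder identifier (recorded in caches/matrices).
#' @slot d integer, output dimension.
#' @slot maxLength integer, sequences are truncated to their first
#'   \code{maxLength} residues before embedding.
#' @slot fun function \code{(sequence, id) -> numeric(d)}; must be
#'   deterministic per sequence.
#'
#' @seealso \code{\link{onehotEmbedder}}, \code{\link{importEmbedder}},
#'   \code{\link{embedDataset}}
#' @exportClass EmbedderSpec
setClass("EmbedderSpec",
  representation(name = "character", d = "integer", maxLength = "integer",
                 fun = "function"))

setValidity("EmbedderSpec", function(object) {
  if (object@d < 1L) return("d must be >= 1")
  if (object@maxLength < 1L) return("maxLength must be >= 1")
  TRUE
})

#' Synthetic-dataset configuration
#'
#' Parameters of the synthetic protein-family generator: families are
#' point-mutant radiations of random seed sequences, each family carries a
#' base optimal pH, and each member receives noisy repeated measurements —
#' the statistical structure the splitting and regression stages assume.
#'
#' @slot nFamilies integer number of families.
#' @slot membersPerFamily integer scalar or length-2 range.
#' @slot seedLength integer residues per family seed sequence.
#' @slot mutationRate per-residue substitution probability for members.
#' @slot phRange length-2 numeric, support of family base pH.
#' @slot neutralFraction probability a family's base pH is drawn from
#'   [6, 8] instead of \code{phRange} (real label sets are concentrated
#'   near neutral pH).
#' @slot labelNoiseSd pH units of Gaussian noise per measurement.
#' @slot measurementsPerRecord integer scalar or length-2 range.
#' @slot rangeFraction fraction of measurements emitted as (lo, hi) ranges.
#' @slot seed integer RNG seed.
#'
#' @seealso \code{\link{simulationConfig}}, \code{\link{simulateDataset}}
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nFamilies = "integer", membersPerFamily = "integer",
                 seedLength = "integer", mutationRate = "numeric",
                 phRange = "numeric", neutralFraction = "numeric",
                 labelNoiseSd = "numeric", measurementsPerRecord = "integer",
                 rangeFraction = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nFamilies < 1L) msg <- c(msg, "nFamilies must be >= 1")
  if (any(object@membersPerFamily < 1L))
    msg <- c(msg, "membersPerFamily must be >= 1")
  if (object@seedLength < 1L) msg <- c(msg, "seedLength must be >= 1")
  if (object@mutationRate < 0 || object@mutationRate > 1)
    msg <- c(msg, "mutationRate must be in [0, 1]")
  if (length(object@phRange) != 2L || object@phRange[1] >= object@phRange[2])
    msg <- c(msg, "phRange must be (lo, hi) with lo < hi")
  if (any(object@phRange < 0) || any(object@phRange > 14))
    msg <- c(msg, "phRange must lie within [0, 14]")
  if (object@neutralFraction < 0 || object@neutralFraction > 1)
    msg <- c(msg, "neutralFraction must be in [0, 1]")
  if (object@labelNoiseSd < 0) msg <- c(msg, "labelNoiseSd must be >= 0")
  if (any(object@measurementsPerRecord < 1L))
    msg <- c(msg, "measurementsPerRecord must be >= 1")
  if (object@rangeFraction < 0 || object@rangeFraction > 1)
    msg <- c(msg, "rangeFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})
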