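# Accessors, constructors and show() methods for the core classes.

#' Construct a labelled dataset
#'
#' @param sequences named \code{AAStringSet} (or named character vector,
#'   which is converted). Optional annotation columns \code{pfam}, \code{ec},
#'   \code{superkingdom} may be present in \code{mcols(sequences)}.
#' @param labels numeric pH labels, either named by id or parallel to
#'   \code{sequences}.
#' @return a \linkS4class{CuratedDataset}.
#' @examples
#' ds <- curatedDataset(c(a = "MKV", b = "MKL"), c(a = 7, b = 5.5))
#' phLabels(ds)
#' @export
curatedDataset <- function(sequences, labels) {
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), names(sequences)))
      stop("label names do not match sequence ids")
    labels <- labels[names(sequences)]
  }
  new("CuratedDataset", sequences = sequences,
      labels = unname(as.numeric(labels)))
}

#' @rdname CuratedDataset-class
#' @export
setMethod("sequences", "CuratedDataset", function(x) x@sequences)

#' @rdname CuratedDataset-class
#' @export
setMethod("phLabels", "CuratedDataset",
  function(x) setNames(x@labels, names(x@sequences)))

#' @rdname CuratedDataset-class
#' @export
setMethod("datasetIds", "CuratedDataset", function(x) names(x@sequences))

#' @rdname CuratedDataset-class
#' @export
setMethod("length", "CuratedDataset", function(x) length(x@sequences))

#' @rdname CuratedDataset-class
#' @param i character, logical or integer index of records to keep.
#' @export
setMethod("[", "CuratedDataset", function(x, i) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  if (anyNA(i)) stop("unknown ids in subset")
  new("CuratedDataset", sequences = x@sequences[i], labels = x@labels[i])
})

#' Annotation accessor
#'
#' Returns one annotation column of a dataset as a named list of character
#' vectors (the \code{";"}-joined storage is split), or \code{NULL} when the
#' column is absent.
#'
#' @param x a \linkS4class{CuratedDataset} or annotated \code{AAStringSet}.
#' @param column one of \code{"pfam"}, \code{"ec"}, \code{"superkingdom"}.
#' @return named list (ids to character vectors), or \code{NULL}.
#' @export
datasetAnnotations <- function(x, column = c("pfam", "ec", "superkingdom")) {
  column <- match.arg(column)
  seqs <- if (is(x, "CuratedDataset")) sequences(x) else x
  mc <- S4Vectors::mcols(seqs)
  if (is.null(mc) || !column %in% colnames(mc)) return(NULL)
  v <- as.character(mc[[column]])
  out <- strsplit(v, ";", fixed = TRUE)
  out <- lapply(out, function(z) z[nzchar(z)])
  names(out) <- names(seqs)
  out[!is.na(v)]
}

setMethod("show", "CuratedDataset", function(object) {
  cat(sprintf("CuratedDataset with %d labelled proteins\n", length(object)))
  cat(sprintf("  pH labels: %.2f .. %.2f (median %.2f)\n",
              min(object@labels), max(object@labels), median(object@labels)))
  mc <- S4Vectors::mcols(object@sequences)
  if (!is.null(mc) && ncol(mc))
    cat("  annotations:", paste(colnames(mc), collapse = ", "), "\n")
})

#' Construct a split assignment
#'
#' @param train,validation,discarded character id vectors.
#' @param folds optional list of character vectors partitioning
#'   \code{validation}.
#' @param strategy label describing how the split was produced.
#' @return a \linkS4class{SplitAssignment}.
#' @export
splitAssignment <- function(train, validation, folds = list(),
                            discarded = character(), strategy = "manual") {
  new("SplitAssignment", train = as.character(train),
      validation = as.character(validation), folds = folds,
      discarded = as.character(discarded), strategy = strategy)
}

#' @rdname SplitAssignment-class
#' @export
setMethod("trainIds", "SplitAssignment", function(x) x@train)

#' @rdname SplitAssignment-class
#' @export
setMethod("validationIds", "SplitAssignment", function(x) x@validation)

#' @rdname SplitAssignment-class
#' @export
setMethod("validationFolds", "SplitAssignment", function(x) x@folds)

#' @rdname SplitAssignment-class
#' @export
setMethod("discardedIds", "SplitAssignment", function(x) x@discarded)

setMethod("show", "SplitAssignment", function(object) {
  cat(sprintf("SplitAssignment (%s): %d train / %d validation",
              object@strategy, length(object@train),
              length(object@validation)))
  if (length(object@folds)) cat(sprintf(" in %d folds", length(object@folds)))
  if (length(object@discarded))
    cat(sprintf(", %d discarded", length(object@discarded)))
  cat("\n")
})

#' @rdname KmerTable-class
#' @param object,x a \linkS4class{KmerTable}.
#' @export
setMethod("kmerSize", "KmerTable", function(x) x@k)

#' @rdname KmerTable-class
#' @export
setMethod("kmerEntries", "KmerTable", function(x) x@entries)

#' @rdname KmerTable-class
#' @export
setMethod("trainMedian", "KmerTable", function(x) x@trainMedian)

setMethod("show", "KmerTable", function(object) {
  cat(sprintf("KmerTable: k = %d, %d distinct k-mers (%s)\n", object@k,
              nrow(object@entries),
              if (object@multiset) "occurrence multiset" else "per-sequence set"))
  cat(sprintf("  train median %.3f; %d training sequences shorter than k\n",
              object@trainMedian, object@skipped))
})

setMethod("show", "PhModel", function(object) {
  cat(sprintf("PhModel <%s> fitted on %d sequences (embedder %s, d = %d)\n",
              object@spec@family, length(object@trainIds),
              object@embedderName, object@d))
})

setMethod("show", "RegressorSpec", function(object) {
  p <- object@params
  ps <- if (length(p))
    paste(names(p), vapply(p, function(z) paste(z, collapse = ","), ""),
          sep = "=", collapse = ", ") else "defaults"
  cat(sprintf("RegressorSpec: %s (%s), seed %d\n",
              object@family, ps, object@seed))
})

#' @rdname EvalReport-class
#' @param object,x an \linkS4class{EvalReport}.
#' @export
setMethod("deltaTable", "EvalReport", function(x) x@deltaTable)

#' @rdname EvalReport-class
#' @export
setMethod("groupTable", "EvalReport", function(x) x@groupTable)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport on %d predictions\n", object@n))
  cat(sprintf("  MAE %.4f, Spearman %s\n", object@mae,
              if (is.na(object@spearman)) "undefined (constant input)"
              else sprintf("%.4f", object@spearman)))
  if (nrow(object@deltaTable)) {
    cat(sprintf("  delta filter (center %.2f):\n", object@center))
    print(object@deltaTable, row.names = FALSE)
  }
  if (nrow(object@groupTable)) {
    cat("  by group:\n")
    print(object@groupTable, row.names = FALSE)
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d families x %s members, seed length %d\n",
    object@nFamilies, paste(object@membersPerFamily, collapse = "-"),
    object@seedLength))
  cat(sprintf(
    "  mutation rate %.3f, base pH U[%.1f, %.1f] (neutral fraction %.2f)\n",
    object@mutationRate, object@phRange[1], object@phRange[2],
    object@neutralFraction))
  cat(sprintf(
    "  %s measurements/record, noise sd %.2f, range fraction %.2f, seed %d\n",
    paste(object@measurementsPerRecord, collapse = "-"),
    object@labelNoiseSd, object@rangeFraction, object@seed))
})
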