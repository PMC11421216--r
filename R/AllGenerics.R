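#' @rdname CuratedDataset-class
#' @param object,x an object.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname CuratedDataset-class
#' @export
setGeneric("phLabels", function(x) standardGeneric("phLabels"))

#' @rdname CuratedDataset-class
#' @export
setGeneric("datasetIds", function(x) standardGeneric("datasetIds"))

#' @rdname SplitAssignment-class
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))

#' @rdname SplitAssignment-class
#' @export
setGeneric("validationIds", function(x) standardGeneric("validationIds"))

#' @rdname SplitAssignment-class
#' @export
setGeneric("validationFolds", function(x) standardGeneric("validationFolds"))

#' @rdname SplitAssignment-class
#' @export
setGeneric("discardedIds", function(x) standardGeneric("discardedIds"))

#' @rdname KmerTable-class
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @rdname KmerTable-class
#' @export
setGeneric("kmerEntries", function(x) standardGeneric("kmerEntries"))

#' @rdname KmerTable-class
#' @export
setGeneric("trainMedian", function(x) standardGeneric("trainMedian"))

#' @rdname EvalReport-class
#' @export
setGeneric("deltaTable", function(x) standardGeneric("deltaTable"))

#' @rdname EvalReport-class
#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))
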