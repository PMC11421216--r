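# Performance metrics and the delta-vicinity filtered evaluation protocol.

#' Mean absolute error
#'
#' @param yTrue,yPred numeric vectors of equal nonzero length.
#' @return mean of \code{|yTrue - yPred|}.
#' @export
maeScore <- function(yTrue, yPred) {
  yTrue <- as.numeric(yTrue); yPred <- as.numeric(yPred)
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) == 0L) stop("empty input")
  mean(abs(yTrue - yPred))
}

#' Spearman rank correlation
#'
#' Both vectors are rank-transformed with average ranks for ties and the
#' product-moment correlation of the ranks is returned; without ties this
#' equals the classical 1 - 6 * sum(d^2) / (n (n^2 - 1)) on the rank
#' differences d. When either vector is constant (e.g. the naive median
#' predictor) the ranks have zero variance and the correlation is undefined:
#' \code{NA} is returned.
#'
#' @param yTrue,yPred numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1], or \code{NA} for constant input.
#' @export
spearmanScore <- function(yTrue, yPred) {
  yTrue <- as.numeric(yTrue); yPred <- as.numeric(yPred)
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) < 2L) stop("need at least two points")
  if (sd(yTrue) == 0 || sd(yPred) == 0) return(NA_real_)
  cor(yTrue, yPred, method = "spearman")
}

#' Delta-vicinity filter
#'
#' Returns the indices of test points whose true label lies at least
#' \code{delta} pH units from the filter center. Most curated labels crowd
#' around neutral pH, where even a constant predictor looks good; removing
#' the center vicinity probes how models extrapolate toward acidic and
#' alkaline optima. The vicinity is open by default: points with
#' \code{|y - center| < delta} are removed, so \code{delta = 0} retains
#' everything.
#'
#' @param yTrue numeric labels.
#' @param center filter center (by convention the training-label median).
#' @param delta vicinity half-width, >= 0.
#' @param boundary \code{"open"} (default; keep \code{>= delta}) or
#'   \code{"closed"} (keep \code{> delta}).
#' @return integer index vector of retained points.
#' @export
deltaFilter <- function(yTrue, center, delta, boundary = c("open", "closed")) {
  boundary <- match.arg(boundary)
  if (delta < 0) stop("delta must be >= 0")
  dist <- abs(as.numeric(yTrue) - center)
  if (boundary == "open") which(dist >= delta) else which(dist > delta)
}

#' Evaluate predictions with the delta-filtered protocol
#'
#' Computes overall MAE and Spearman correlation, then recomputes both on
#' the subsets retained by \code{\link{deltaFilter}} for each \code{delta},
#' and optionally stratifies the overall metrics by a grouping label (e.g.
#' superkingdom). The filter center is the training-label median passed by
#' the caller — using the training median rather than a pooled median keeps
#' test labels out of the protocol's own parameters.
#'
#' @param yTrue,yPred aligned numeric vectors.
#' @param trainMedian filter center for the delta protocol.
#' @param deltas vicinity half-widths (default \code{c(0, 0.5, 1, 1.5)}).
#' @param groups optional character/factor vector parallel to \code{yTrue}
#'   for stratified reporting.
#' @param boundary vicinity boundary convention, see
#'   \code{\link{deltaFilter}}.
#' @return an \linkS4class{EvalReport}. Per delta, MAE is reported when at
#'   least one point survives and Spearman when at least two do (NA
#'   otherwise).
#' @export
evaluatePredictions <- function(yTrue, yPred, trainMedian,
                                deltas = c(0, 0.5, 1, 1.5), groups = NULL,
                                boundary = "open") {
  yTrue <- as.numeric(yTrue); yPred <- as.numeric(yPred)
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) == 0L) stop("empty input")
  overallMae <- maeScore(yTrue, yPred)
  overallSp <- if (length(yTrue) >= 2L) spearmanScore(yTrue, yPred)
               else NA_real_
  deltaRows <- lapply(sort(deltas), function(d) {
    idx <- deltaFilter(yTrue, trainMedian, d, boundary)
    data.frame(delta = d, nKept = length(idx),
               mae = if (length(idx) >= 1L)
                 maeScore(yTrue[idx], yPred[idx]) else NA_real_,
               spearman = if (length(idx) >= 2L)
                 spearmanScore(yTrue[idx], yPred[idx]) else NA_real_)
  })
  groupRows <- data.frame(group = character(), n = integer(),
                          mae = numeric(), spearman = numeric())
  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (length(groups) != length(yTrue))
      stop("groups must be parallel to yTrue")
    groupRows <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
      idx <- which(groups == g)
      data.frame(group = g, n = length(idx),
                 mae = maeScore(yTrue[idx], yPred[idx]),
                 spearman = if (length(idx) >= 2L)
                   spearmanScore(yTrue[idx], yPred[idx]) else NA_real_)
    }))
  }
  new("EvalReport", n = length(yTrue), mae = overallMae,
      spearman = overallSp, center = as.numeric(trainMedian),
      deltaTable = do.call(rbind, deltaRows), groupTable = groupRows)
}
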