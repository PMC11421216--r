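# Curation of raw pH observations into one optimal-pH label per protein,
# and aggregation of environmental growth-pH measurements over organisms.

#' Midpoint of an optimal-pH range
#'
#' Range observations are reduced to the average of the lower and upper
#' boundary before pooling with point observations.
#'
#' @param lo,hi numeric pH bounds, \code{lo <= hi}, both in [0, 14].
#'   Vectorized.
#' @return \code{(lo + hi) / 2}.
#' @examples
#' rangeMidpoint(6, 8) # 7
#' @export
rangeMidpoint <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  .checkPh(lo, "pH range bound"); .checkPh(hi, "pH range bound")
  if (any(lo > hi)) stop("pH range with lo > hi")
  (lo + hi) / 2
}

#' Curate optimal-pH labels from raw measurements
#'
#' Per protein id, range observations are replaced by their midpoints and
#' pooled with point observations. If the pooled values have population
#' standard deviation greater than \code{stdThreshold} the protein is
#' discarded (its repeated measurements disagree too much to define one
#' optimum); otherwise its label is the arithmetic mean of the pooled
#' values. Proteins without measurements are absent from the result.
#'
#' @param measurements data.frame as returned by
#'   \code{\link{readMeasurementTable}} (validated with
#'   \code{\link{measurementTable}}).
#' @param records named \code{AAStringSet} covering every measured id.
#' @param stdThreshold discard threshold on the population standard
#'   deviation of an id's pooled values (default 1.0 pH units; strict
#'   \code{>} comparison, so single measurements are always kept).
#' @return a \linkS4class{CuratedDataset}; the ids dropped by the standard
#'   deviation filter are recorded in \code{attr(x, "discarded")}.
#' @examples
#' seqs <- Biostrings::AAStringSet(c(a = "MKVL", b = "MKWW"))
#' m <- measurementTable(data.frame(id = c("a", "a", "b", "b"),
#'                                  ph = c(7, 7.4, 6, 9)))
#' ds <- curateOptimalPh(m, seqs)   # b dropped: population std 1.5 > 1
#' phLabels(ds)
#' @export
curateOptimalPh <- function(measurements, records, stdThreshold = 1.0) {
  measurements <- measurementTable(measurements)
  missing <- setdiff(measurements$id, names(records))
  if (length(missing))
    stop("measured ids missing from records: ",
         paste(missing, collapse = ", "))
  isRange <- is.finite(measurements$ph_lo)
  value <- measurements$ph
  value[isRange] <- rangeMidpoint(measurements$ph_lo[isRange],
                                  measurements$ph_hi[isRange])
  pooled <- split(value, measurements$id)
  sds <- vapply(pooled, popSd, 0)
  keep <- sds <= stdThreshold
  labels <- vapply(pooled[keep], mean, 0)
  ord <- names(records)[names(records) %in% names(labels)]
  out <- curatedDataset(records[ord], labels[ord])
  attr(out, "discarded") <- names(pooled)[!keep]
  out
}

#' Aggregate growth-pH measurements over organisms (mean growth pH)
#'
#' A protein observed in several organisms gets, per organism, the mean of
#' that organism's measurements; the protein's mean growth pH is the
#' unweighted mean of these per-organism means, so organisms with many
#' measurements do not dominate. The standard-deviation discard (population
#' std of the per-organism means > threshold) is applied by
#' \code{\link{curateGrowthPh}}, not here.
#'
#' @param observations named list mapping organism to a numeric vector of
#'   pH measurements for one protein.
#' @return the mean growth pH.
#' @examples
#' aggregateGrowthPh(list(orgA = c(6, 8), orgB = 5)) # (7 + 5) / 2 = 6
#' @export
aggregateGrowthPh <- function(observations) {
  if (length(observations) == 0L ||
      any(vapply(observations, length, 0L) == 0L))
    stop("at least one organism with at least one measurement is required")
  perOrganism <- vapply(observations, function(v) mean(as.numeric(v)), 0)
  mean(perOrganism)
}

#' Curate mean-growth-pH labels
#'
#' Applies \code{\link{aggregateGrowthPh}} per protein and discards proteins
#' whose per-organism means have population standard deviation greater than
#' \code{stdThreshold}.
#'
#' @inheritParams curateOptimalPh
#' @param measurements measurement table with an \code{organism} column and
#'   point observations.
#' @return a \linkS4class{CuratedDataset} with growth-pH labels;
#'   dropped ids in \code{attr(x, "discarded")}.
#' @export
curateGrowthPh <- function(measurements, records, stdThreshold = 1.0) {
  measurements <- measurementTable(measurements)
  if (any(is.na(measurements$organism)))
    stop("growth-pH curation requires an organism for every row")
  if (any(is.finite(measurements$ph_lo)))
    stop("growth-pH curation expects point observations only")
  missing <- setdiff(measurements$id, names(records))
  if (length(missing))
    stop("measured ids missing from records: ",
         paste(missing, collapse = ", "))
  byId <- split(measurements[c("ph", "organism")], measurements$id)
  labels <- vapply(byId, function(df) {
    aggregateGrowthPh(split(df$ph, df$organism))
  }, 0)
  orgMeanSd <- vapply(byId, function(df) {
    popSd(vapply(split(df$ph, df$organism), mean, 0))
  }, 0)
  keep <- orgMeanSd <= stdThreshold
  ord <- names(records)[names(records) %in% names(labels)[keep]]
  out <- curatedDataset(records[ord], labels[ord])
  attr(out, "discarded") <- names(byId)[!keep]
  out
}
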