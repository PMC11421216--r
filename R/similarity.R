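# Pairwise sequence-identity similarity and its distance transform, the
# inputs of the homology split.

#' Normalized pairwise identity of two sequences
#'
#' Scores an optimal global alignment with match = 1, mismatch = 0 and gap
#' penalty 0 — i.e. the maximal number of identical residue pairs any
#' alignment can realize — and divides by the length of the shorter raw
#' sequence. Normalizing by the shorter sequence makes the criterion strict:
#' a short perfect fragment of a long protein still scores 1.
#'
#' @param a,b amino-acid strings (nonempty).
#' @return identity score in [0, 1].
#' @examples
#' alignmentIdentity("MKVL", "MKWW") # 2 matches / 4 = 0.5
#' @export
alignmentIdentity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  .identityScore(a, b) / min(nchar(a), nchar(b))
}

#' All-vs-all normalized identity matrix
#'
#' @param records named \code{AAStringSet}, named character vector, or
#'   \linkS4class{CuratedDataset} with at least two records.
#' @return symmetric numeric matrix S with unit diagonal, entries in [0, 1],
#'   dimnames = record ids. A precomputed matrix (e.g. MSA-derived scores
#'   read with \code{\link{readMatrixFile}}) can be used in its place
#'   anywhere the package takes a similarity matrix.
#' @seealso \code{\link{similarityToDistance}}, \code{\link{densityCluster}}
#' @export
pairwiseSimilarity <- function(records) {
  if (is(records, "CuratedDataset")) records <- sequences(records)
  seqs <- toupper(as.character(records))
  if (length(seqs) < 2L) stop("need at least two records")
  if (any(!nzchar(seqs)))
    stop("empty sequence for id: ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  S <- .identityMatrix(seqs)
  dimnames(S) <- list(names(seqs), names(seqs))
  S
}

.checkSquare <- function(m, what) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix")
  if (is.null(rownames(m)))
    stop(what, " must carry ids as dimnames")
  if (max(abs(m - t(m))) > 1e-8) stop(what, " must be symmetric")
  invisible(m)
}

#' Distance matrix from a similarity matrix
#'
#' Elementwise complement D = 1 - S (the all-ones matrix minus the
#' similarity matrix), with the diagonal forced to zero.
#'
#' @param S symmetric similarity matrix with entries in [0, 1] and unit
#'   diagonal (see \code{\link{pairwiseSimilarity}}).
#' @return distance matrix D with zero diagonal and entries in [0, 1].
#' @export
similarityToDistance <- function(S) {
  .checkSquare(S, "similarity matrix")
  if (any(S < -1e-8) || any(S > 1 + 1e-8))
    stop("similarity entries must lie in [0, 1]")
  D <- 1 - S
  D[D < 0] <- 0
  diag(D) <- 0
  D
}
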