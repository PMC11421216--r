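# The two-step k-mer baseline: (1) summarize training labels per k-mer,
# (2) predict a query as the occurrence-weighted average of its k-mers'
# summaries.

.kmersOf <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character())
  substring(seq, seq_len(L - k + 1L), k:L)
}

#' Build a k-mer pH summary table
#'
#' Every training sequence is decomposed into its length-k subsequences and
#' each k-mer occurrence is associated with that sequence's pH label; per
#' distinct k-mer the mean, minimum and maximum of its associated labels are
#' stored. This aggregation runs once per training set; prediction then only
#' looks entries up. Training sequences shorter than k are skipped and
#' counted. The vocabulary is open (noncanonical residues form k-mers
#' verbatim) and stored sparsely; absent k-mers are treated as 0 at
#' prediction time.
#'
#' @param train a \linkS4class{CuratedDataset}.
#' @param k k-mer length (default 3).
#' @param multiset if \code{TRUE} (default) every occurrence of a k-mer in
#'   a sequence contributes one copy of its label, mirroring the
#'   occurrence-counting query side; if \code{FALSE} each distinct k-mer of
#'   a sequence contributes once (strict set reading).
#' @return a \linkS4class{KmerTable}.
#' @examples
#' ds <- curatedDataset(c(s1 = "AAC", s2 = "CAA"), c(s1 = 4, s2 = 8))
#' tab <- buildKmerTable(ds, k = 2)
#' kmerEntries(tab)  # AA appears in both: mean 6, min 4, max 8
#' @export
buildKmerTable <- function(train, k = 3L, multiset = TRUE) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (!is(train, "CuratedDataset") || length(train) == 0L)
    stop("a nonempty CuratedDataset is required")
  seqs <- as.character(sequences(train))
  labels <- phLabels(train)
  usable <- nchar(seqs) >= k
  skipped <- sum(!usable)
  if (skipped > 0L)
    warning(sprintf("%d training sequence(s) shorter than k = %d skipped",
                    skipped, k))
  if (!any(usable)) {
    entries <- data.frame(kmer = character(), mean = numeric(),
                          min = numeric(), max = numeric(),
                          count = integer())
  } else {
    pieces <- lapply(which(usable), function(i) {
      km <- .kmersOf(seqs[i], k)
      if (!multiset) km <- unique(km)
      list(kmer = km, ph = rep(labels[i], length(km)))
    })
    dt <- data.table::data.table(
      kmer = unlist(lapply(pieces, `[[`, "kmer"), use.names = FALSE),
      ph = unlist(lapply(pieces, `[[`, "ph"), use.names = FALSE))
    agg <- dt[, list(mean = mean(ph), min = min(ph), max = max(ph),
                     count = .N), by = "kmer"]
    data.table::setorder(agg, kmer)
    entries <- as.data.frame(agg)
  }
  new("KmerTable", k = k, entries = entries,
      trainMedian = median(unname(labels)), skipped = as.integer(skipped),
      multiset = isTRUE(multiset))
}

.kmerPredictOne <- function(values, found, n, mode, fallback) {
  if (mode == "literal") {
    list(value = sum(values) / n, fallback = FALSE)
  } else {
    if (!any(found)) list(value = fallback, fallback = TRUE)
    else list(value = sum(values[found]) / sum(found), fallback = FALSE)
  }
}

.kmerPredict <- function(table, sequences, mode, column) {
  mode <- match.arg(mode, c("literal", "present_only"))
  seqs <- if (is(sequences, "AAStringSet")) as.character(sequences)
          else as.character(sequences)
  if (is.null(names(seqs)) && !is.null(names(sequences)))
    names(seqs) <- names(sequences)
  k <- table@k
  if (any(nchar(seqs) < k))
    stop("query sequence(s) shorter than k = ", k)
  entries <- table@entries
  out <- numeric(length(seqs))
  fb <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    occ <- .kmersOf(toupper(seqs[i]), k)
    idx <- match(occ, entries$kmer)
    found <- !is.na(idx)
    values <- numeric(length(occ))
    values[found] <- entries[[column]][idx[found]]
    r <- .kmerPredictOne(values, found, length(occ), mode, table@trainMedian)
    out[i] <- r$value
    fb[i] <- r$fallback
  }
  names(out) <- names(seqs)
  attr(out, "fallback") <- setNames(fb, names(seqs))
  out
}

#' Predict optimal pH with the k-mer table
#'
#' A query of length L holds N = L - k + 1 k-mer occurrences. In
#' \code{"literal"} mode the prediction is the sum of the table's mean-pH
#' entries over all occurrences (0 for k-mers absent from the table),
#' divided by N — the sparse dot product (P . T) / N where P counts the
#' query's k-mer occurrences and T holds the per-k-mer training means. In
#' \code{"present_only"} mode the denominator counts only occurrences found
#' in the table, so unseen k-mers no longer drag the prediction toward 0;
#' a query sharing no k-mer with the table falls back to the training-label
#' median and is flagged.
#'
#' @param table a \linkS4class{KmerTable}.
#' @param sequences character vector or \code{AAStringSet} of queries, each
#'   of length >= k.
#' @param mode \code{"literal"} (the faithful sparse dot product) or
#'   \code{"present_only"} (recommended in practice; see the vignette).
#' @return named numeric vector of pH predictions with a logical
#'   \code{attr(x, "fallback")} marking median fallbacks.
#' @export
predictKmerPh <- function(table, sequences,
                          mode = c("literal", "present_only")) {
  .kmerPredict(table, sequences, match.arg(mode), "mean")
}

#' Predict an optimal-pH range with the k-mer table
#'
#' Applies the same averaging as \code{\link{predictKmerPh}} to the
#' per-k-mer minimum and maximum label entries, giving a lower and upper
#' bound of the expected optimum.
#'
#' @inheritParams predictKmerPh
#' @return two-column matrix (\code{lo}, \code{hi}), one row per query,
#'   with \code{attr(x, "fallback")} as in \code{\link{predictKmerPh}}.
#' @export
predictKmerRange <- function(table, sequences,
                             mode = c("literal", "present_only")) {
  mode <- match.arg(mode)
  lo <- .kmerPredict(table, sequences, mode, "min")
  hi <- .kmerPredict(table, sequences, mode, "max")
  out <- cbind(lo = unname(lo), hi = unname(hi))
  rownames(out) <- names(lo)
  attr(out, "fallback") <- attr(lo, "fallback")
  out
}

#' Write a k-mer table to delimited text
#'
#' One header comment line records k, the training median, the multiset
#' flag and the skipped-sequence count; the body is a tab-separated table
#' (kmer, mean, min, max, count).
#'
#' @param table a \linkS4class{KmerTable}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeKmerTable <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#k=%d train_median=%.17g multiset=%s skipped=%d",
                     table@k, table@trainMedian,
                     if (table@multiset) "TRUE" else "FALSE",
                     table@skipped), con)
  utils::write.table(table@entries, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a k-mer table written by \code{\link{writeKmerTable}}
#'
#' @param path file path.
#' @return a \linkS4class{KmerTable}.
#' @export
readKmerTable <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#k="))
    stop("not a k-mer table file: ", path)
  fields <- strsplit(sub("^#", "", header), " ")[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  entries <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                               stringsAsFactors = FALSE, comment.char = "",
                               colClasses = c(kmer = "character"))
  new("KmerTable", k = as.integer(meta[["k"]]), entries = entries,
      trainMedian = as.numeric(meta[["train_median"]]),
      skipped = as.integer(meta[["skipped"]]),
      multiset = identical(meta[["multiset"]], "TRUE"))
}
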