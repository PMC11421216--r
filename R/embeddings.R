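# Fixed-length numeric representations of sequences: the built-in averaged
# one-hot encoder, an importer for precomputed embedding tables, and the
# adapter contract external embedders plug into.

#' Canonical amino-acid alphabet used by the one-hot encoder
#' @export
CANONICAL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Truncate a sequence to its first residues
#'
#' Long sequences are cut to their first \code{maxLength} residues before
#' embedding (fixed-budget backends cannot process arbitrary lengths);
#' shorter sequences pass unchanged.
#'
#' @param sequences character vector or \code{AAStringSet}.
#' @param maxLength maximum retained length (default 5000).
#' @return object of the input type; the number of truncated sequences is
#'   attached as \code{attr(x, "nTruncated")}.
#' @export
truncateSequence <- function(sequences, maxLength = 5000L) {
  maxLength <- as.integer(maxLength)
  if (maxLength < 1L) stop("maxLength must be >= 1")
  if (is(sequences, "XStringSet")) {
    w <- Biostrings::width(sequences)
    out <- Biostrings::subseq(sequences, 1L, pmin(w, maxLength))
    attr(out, "nTruncated") <- sum(w > maxLength)
  } else {
    w <- nchar(sequences)
    out <- substr(sequences, 1L, maxLength)
    attr(out, "nTruncated") <- sum(w > maxLength)
  }
  out
}

#' Averaged one-hot embedding of one sequence
#'
#' Each position contributes a one-hot row over the canonical 20-letter
#' alphabet (fixed order \code{ACDEFGHIKLMNPQRSTVWY}); rows are averaged
#' over all positions, giving the sequence's residue-composition vector.
#' Noncanonical symbols (X, B, Z, U, O, ...) contribute an all-zero row but
#' still count in the denominator, so the entries sum to the canonical
#' fraction of the sequence (<= 1). With \code{unknownChannel = TRUE} a 21st
#' channel collects all noncanonical positions instead (entries then sum to
#' 1).
#'
#' @param sequence nonempty amino-acid string.
#' @param unknownChannel add a 21st channel for noncanonical residues.
#' @return named numeric vector of length 20 (or 21).
#' @examples
#' onehotEmbed("AC")  # 0.5 at A, 0.5 at C
#' @export
onehotEmbed <- function(sequence, unknownChannel = FALSE) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("a single nonempty sequence is required")
  chars <- strsplit(sequence, "")[[1]]
  alphabet <- if (unknownChannel) c(CANONICAL_AA, "X") else CANONICAL_AA
  if (unknownChannel) chars[!chars %in% CANONICAL_AA] <- "X"
  counts <- table(factor(chars, levels = alphabet))
  setNames(as.numeric(counts) / length(chars), alphabet)
}

#' Built-in averaged one-hot embedder
#'
#' @param maxLength truncation limit applied before embedding.
#' @param unknownChannel see \code{\link{onehotEmbed}}.
#' @return an \linkS4class{EmbedderSpec} of dimension 20 (or 21).
#' @export
onehotEmbedder <- function(maxLength = 5000L, unknownChannel = FALSE) {
  d <- if (unknownChannel) 21L else 20L
  new("EmbedderSpec",
      name = if (unknownChannel) "onehot21" else "onehot",
      d = d, maxLength = as.integer(maxLength),
      fun = function(sequence, id) onehotEmbed(sequence, unknownChannel))
}

#' Embedder backed by a precomputed embedding table
#'
#' Wraps a matrix of externally computed embeddings (e.g. exported from a
#' protein language model) as an \linkS4class{EmbedderSpec}; rows are looked
#' up by record id.
#'
#' @param source path to a delimited table (first column id, remaining
#'   columns the embedding) or a numeric matrix with ids as rownames.
#' @param name embedder name recorded in the resulting matrices (should
#'   identify the model and its pooling, e.g. \code{"esm2_meanpool"}).
#' @return an \linkS4class{EmbedderSpec}.
#' @export
importEmbedder <- function(source, name = "imported") {
  X <- if (is.character(source)) readEmbeddingMatrix(source) else source
  if (!is.matrix(X) || is.null(rownames(X)))
    stop("precomputed embeddings must be a matrix with ids as rownames")
  new("EmbedderSpec", name = name, d = ncol(X),
      maxLength = .Machine$integer.max,
      fun = function(sequence, id) {
        if (!id %in% rownames(X))
          stop("no precomputed embedding for id: ", id)
        as.numeric(X[id, ])
      })
}

#' Custom embedder adapter
#'
#' The uniform contract external backends satisfy: any deterministic
#' function from a (truncated) sequence to a fixed-length numeric vector.
#'
#' @param name backend name (record the pooling choice here).
#' @param d output dimension.
#' @param fun function \code{(sequence, id) -> numeric(d)}.
#' @param maxLength truncation limit (default 5000).
#' @return an \linkS4class{EmbedderSpec}.
#' @export
customEmbedder <- function(name, d, fun, maxLength = 5000L) {
  new("EmbedderSpec", name = name, d = as.integer(d),
      maxLength = as.integer(maxLength), fun = fun)
}

#' Embed a dataset
#'
#' Applies an embedder to every record (after truncation to the embedder's
#' \code{maxLength}) and stacks the vectors into an n x d matrix. When
#' \code{cachePath} is given and holds a matrix for the same ids (same
#' order) and the same embedder, the cached matrix is returned without
#' recomputation; otherwise the result is (re)written there.
#'
#' @param records named \code{AAStringSet} or \linkS4class{CuratedDataset}.
#' @param spec an \linkS4class{EmbedderSpec} (default: one-hot).
#' @param cachePath optional path for the embedding cache (delimited text).
#' @return numeric matrix with record ids as rownames and
#'   \code{attr(x, "embedder")} naming the backend.
#' @export
embedDataset <- function(records, spec = onehotEmbedder(),
                         cachePath = NULL) {
  if (is(records, "CuratedDataset")) records <- sequences(records)
  if (length(records) == 0L) stop("no records to embed")
  if (!is(spec, "EmbedderSpec")) stop("spec must be an EmbedderSpec")
  ids <- names(records)
  if (!is.null(cachePath) && file.exists(cachePath)) {
    cached <- tryCatch(readEmbeddingMatrix(cachePath), error = function(e) NULL)
    if (!is.null(cached) && identical(rownames(cached), ids) &&
        identical(attr(cached, "embedder"), spec@name) &&
        ncol(cached) == spec@d)
      return(cached)
  }
  seqs <- as.character(truncateSequence(records, spec@maxLength))
  X <- matrix(NA_real_, nrow = length(ids), ncol = spec@d,
              dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    v <- spec@fun(seqs[i], ids[i])
    if (length(v) != spec@d)
      stop(sprintf("embedder '%s' returned length %d for id %s (expected %d)",
                   spec@name, length(v), ids[i], spec@d))
    if (any(!is.finite(v)))
      stop("non-finite embedding for id: ", ids[i])
    X[i, ] <- as.numeric(v)
  }
  attr(X, "embedder") <- spec@name
  if (!is.null(cachePath)) writeEmbeddingMatrix(X, cachePath)
  X
}

#' Write an embedding matrix
#'
#' Header comment records the embedder name and dimension; body is a
#' tab-separated table with the id column first.
#'
#' @param X embedding matrix with ids as rownames.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEmbeddingMatrix <- function(X, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#embedder=%s d=%d",
                     attr(X, "embedder") %||% "unknown", ncol(X)), con)
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  colnames(df) <- c("id", paste0("e", seq_len(ncol(X))))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding matrix written by \code{\link{writeEmbeddingMatrix}}
#'
#' @param path file path.
#' @return numeric matrix with ids as rownames and \code{attr "embedder"}.
#' @export
readEmbeddingMatrix <- function(path) {
  header <- readLines(path, n = 1L)
  skip <- 0L
  name <- "unknown"
  if (startsWith(header, "#embedder=")) {
    skip <- 1L
    name <- sub(" .*$", "", sub("^#embedder=", "", header))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                          stringsAsFactors = FALSE, comment.char = "")
  X <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(X) <- list(as.character(df[[1L]]), NULL)
  storage.mode(X) <- "double"
  attr(X, "embedder") <- name
  X
}
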