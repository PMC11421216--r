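# Readers and writers for the external plain-text interfaces: FASTA
# sequences, measurement / label / annotation tables, square matrices and
# split files. Delimited tables are comma- or tab-separated with a header;
# the delimiter is auto-detected.

.detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty table file: ", path)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .detectSep(path),
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          comment.char = "", quote = "\"")
  names(df) <- tolower(trimws(names(df)))
  df
}

.checkPh <- function(x, what) {
  bad <- is.finite(x) & (x < 0 | x > 14)
  if (any(bad))
    stop(sprintf("%s outside [0, 14]: %s", what,
                 paste(unique(x[bad]), collapse = ", ")))
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' The header token before the first whitespace becomes the record id;
#' sequences are uppercased. Gap characters (\code{-}, \code{.}) are
#' rejected; noncanonical residues (X, B, Z, U, O) are tolerated.
#'
#' @param path FASTA file path.
#' @return named \code{AAStringSet}, one entry per FASTA record.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1 some description", "MKV"), f)
#' readFastaProteins(f)
#' @export
readFastaProteins <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (length(nonEmpty) == 0L) return(Biostrings::AAStringSet())
  if (!startsWith(trimws(lines[nonEmpty[1]]), ">"))
    stop(sprintf("malformed FASTA: line %d is not a header", nonEmpty[1]))
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  if (any(!nzchar(names(seqs))))
    stop("malformed FASTA: empty record id")
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    stop("duplicate ids in FASTA: ", paste(dup, collapse = ", "))
  chars <- as.character(seqs)
  if (any(grepl("[-. \t]", chars)))
    stop("sequences must not contain gap or whitespace characters: ",
         paste(names(seqs)[grepl("[-. \t]", chars)], collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence for id: ",
         paste(names(seqs)[Biostrings::width(seqs) == 0L], collapse = ", "))
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs named \code{AAStringSet} or named character vector.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFastaProteins <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a pH measurement table
#'
#' Expects a delimited text file with a header and columns \code{id} plus
#' either \code{ph} (point measurements) or \code{ph_lo}/\code{ph_hi}
#' (range measurements) or all three (mixed rows: a row uses the point
#' column or the range columns); an \code{organism} column is optional and
#' used only for growth-pH aggregation.
#'
#' @param path file path.
#' @return data.frame with columns \code{id}, \code{ph}, \code{ph_lo},
#'   \code{ph_hi}, \code{organism} (\code{NA} where not applicable), one row
#'   per observation.
#' @export
readMeasurementTable <- function(path) {
  df <- .readTable(path)
  if (!"id" %in% names(df)) stop("measurement table needs an 'id' column")
  hasPoint <- "ph" %in% names(df)
  hasRange <- all(c("ph_lo", "ph_hi") %in% names(df))
  if (!hasPoint && !hasRange)
    stop("measurement table needs 'ph' or 'ph_lo'+'ph_hi' columns")
  out <- data.frame(id = as.character(df$id),
                    ph = if (hasPoint) as.numeric(df$ph) else NA_real_,
                    ph_lo = if (hasRange) as.numeric(df$ph_lo) else NA_real_,
                    ph_hi = if (hasRange) as.numeric(df$ph_hi) else NA_real_,
                    organism = if ("organism" %in% names(df))
                      as.character(df$organism) else NA_character_,
                    stringsAsFactors = FALSE)
  measurementTable(out)
}

#' Validate a measurement table
#'
#' Checks the invariants of raw measurement rows: every pH value in
#' [0, 14], ranges with \code{lo <= hi}, and exactly one of point value or
#' range per row.
#'
#' @param df data.frame with columns \code{id} and \code{ph} and/or
#'   \code{ph_lo}, \code{ph_hi}, optional \code{organism}.
#' @return the validated, normalized data.frame.
#' @export
measurementTable <- function(df) {
  for (col in c("ph", "ph_lo", "ph_hi"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  if (!"organism" %in% names(df)) df$organism <- NA_character_
  df$id <- as.character(df$id)
  isPoint <- is.finite(df$ph)
  isRange <- is.finite(df$ph_lo) & is.finite(df$ph_hi)
  if (any(isPoint & isRange))
    stop("rows with both a point value and a range: ",
         paste(unique(df$id[isPoint & isRange]), collapse = ", "))
  if (any(!isPoint & !isRange))
    stop("rows with neither a point value nor a complete range: ",
         paste(unique(df$id[!isPoint & !isRange]), collapse = ", "))
  .checkPh(df$ph, "pH value")
  .checkPh(df$ph_lo, "pH range bound")
  .checkPh(df$ph_hi, "pH range bound")
  bad <- isRange & df$ph_lo > df$ph_hi
  if (any(bad))
    stop("pH ranges with lo > hi for: ",
         paste(unique(df$id[bad]), collapse = ", "))
  df[c("id", "ph", "ph_lo", "ph_hi", "organism")]
}

#' Read an annotation table
#'
#' Two-column delimited text (\code{id}, annotation) where multiple
#' annotations per id are \code{";"}-joined. Used for PFAM accessions, EC
#' numbers and superkingdom labels.
#'
#' @param path file path.
#' @param column annotation column name in the file (default: the second
#'   column, whatever its name).
#' @return named list mapping id to a character vector of annotations.
#' @export
readAnnotationTable <- function(path, column = NULL) {
  df <- .readTable(path)
  if (!"id" %in% names(df)) stop("annotation table needs an 'id' column")
  if (is.null(column)) column <- setdiff(names(df), "id")[1]
  column <- tolower(column)
  if (is.na(column) || !column %in% names(df))
    stop("annotation column not found in ", path)
  vals <- strsplit(as.character(df[[column]]), ";", fixed = TRUE)
  vals <- lapply(vals, function(z) trimws(z[nzchar(trimws(z))]))
  setNames(vals, as.character(df$id))
}

#' Read curated labels
#'
#' @param path delimited text with columns \code{id}, \code{ph}.
#' @return named numeric vector of labels.
#' @export
readLabelTable <- function(path) {
  df <- .readTable(path)
  if (!all(c("id", "ph") %in% names(df)))
    stop("label table needs 'id' and 'ph' columns")
  .checkPh(as.numeric(df$ph), "label")
  setNames(as.numeric(df$ph), as.character(df$id))
}

#' Write curated labels
#'
#' @param labels named numeric vector or \linkS4class{CuratedDataset}.
#' @param path output file (tab-separated, columns \code{id}, \code{ph}).
#' @return \code{path}, invisibly.
#' @export
writeLabelTable <- function(labels, path) {
  if (is(labels, "CuratedDataset")) labels <- phLabels(labels)
  df <- data.frame(id = names(labels), ph = as.numeric(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square matrix with id header row and column
#'
#' Accepts precomputed similarity or distance matrices so externally derived
#' scores (e.g. from an MSA) can replace the built-in aligner.
#'
#' @param path delimited numeric text; first column holds row ids, header
#'   holds column ids.
#' @return numeric matrix with matching dimnames.
#' @export
readMatrixFile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .detectSep(path),
                          row.names = 1L, check.names = FALSE,
                          comment.char = "")
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("matrix file must be square with identical row and column ids")
  storage.mode(m) <- "double"
  m
}

#' Write a square matrix with id header row and column
#'
#' @param m numeric matrix with dimnames.
#' @param path output file (tab-separated).
#' @return \code{path}, invisibly.
#' @export
writeMatrixFile <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a split assignment
#'
#' Rows are (id, role, fold) with role in train/validation/discarded and
#' fold the 1-based validation fold index (empty when the split has no fold
#' structure). Rows are written in sorted id order so equal splits produce
#' byte-identical files.
#'
#' @param split a \linkS4class{SplitAssignment}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSplitAssignment <- function(split, path) {
  foldOf <- rep(NA_integer_, length(validationIds(split)))
  names(foldOf) <- validationIds(split)
  for (i in seq_along(split@folds)) foldOf[split@folds[[i]]] <- i
  df <- rbind(
    data.frame(id = trainIds(split), role = "train", fold = NA_integer_),
    data.frame(id = validationIds(split), role = "validation",
               fold = unname(foldOf)),
    if (length(discardedIds(split)))
      data.frame(id = discardedIds(split), role = "discarded",
                 fold = NA_integer_))
  df <- df[order(df$id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a split assignment
#'
#' @param path file written by \code{\link{writeSplitAssignment}}.
#' @return a \linkS4class{SplitAssignment}.
#' @export
readSplitAssignment <- function(path) {
  df <- .readTable(path)
  if (!all(c("id", "role") %in% names(df)))
    stop("split file needs 'id' and 'role' columns")
  val <- df$id[df$role == "validation"]
  folds <- list()
  if ("fold" %in% names(df)) {
    fv <- suppressWarnings(as.integer(df$fold[df$role == "validation"]))
    if (any(!is.na(fv)))
      folds <- lapply(sort(unique(fv[!is.na(fv)])),
                      function(i) val[which(fv == i)])
  }
  splitAssignment(train = df$id[df$role == "train"], validation = val,
                  folds = folds, discarded = df$id[df$role == "discarded"],
                  strategy = "file")
}
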