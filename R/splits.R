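# Random, PFAM hold-out and EC-class splits, plus homology-guarded
# enrichment of an existing training side.

#' Random train/validation split
#'
#' @param dataset a \linkS4class{CuratedDataset} with at least two records.
#' @param validationFraction share of records held out for validation
#'   (default 0.25, a 3:1 train:validation ratio).
#' @param seed integer seed; the assignment is deterministic per seed.
#' @return a \linkS4class{SplitAssignment} with
#'   \code{round(n * validationFraction)} validation ids.
#' @export
randomSplit <- function(dataset, validationFraction = 0.25, seed = 1L) {
  if (length(dataset) < 2L) stop("need at least two records to split")
  if (validationFraction <= 0 || validationFraction >= 1)
    stop("validationFraction must lie in (0, 1)")
  ids <- datasetIds(dataset)
  nVal <- round(length(ids) * validationFraction)
  if (nVal < 1L || nVal >= length(ids))
    stop("validationFraction leaves one side empty for this dataset size")
  val <- withr::with_seed(as.integer(seed), sample(ids, nVal))
  splitAssignment(train = setdiff(ids, val), validation = val,
                  strategy = "random")
}

#' PFAM hold-out splits
#'
#' One split per distinct PFAM accession: every sequence annotated with that
#' accession forms the validation set and all other sequences (including
#' unannotated ones) form the training set. Accessions whose validation set
#' would be empty or would swallow the whole dataset are skipped and
#' reported.
#'
#' @param dataset a \linkS4class{CuratedDataset}.
#' @param pfamAnnotations named list mapping id to a character vector of
#'   PFAM accessions; defaults to the dataset's own \code{pfam} annotation
#'   column.
#' @return named list of \linkS4class{SplitAssignment}s (one per PFAM
#'   accession, sorted); skipped accessions with reasons in
#'   \code{attr(x, "skipped")}.
#' @export
pfamHoldoutSplits <- function(dataset, pfamAnnotations = NULL) {
  if (is.null(pfamAnnotations))
    pfamAnnotations <- datasetAnnotations(dataset, "pfam")
  if (is.null(pfamAnnotations) || !length(pfamAnnotations))
    stop("no PFAM annotations available")
  ids <- datasetIds(dataset)
  ann <- pfamAnnotations[names(pfamAnnotations) %in% ids]
  long <- data.frame(
    id = rep(names(ann), lengths(ann)),
    pfam = unlist(ann, use.names = FALSE))
  splits <- list()
  skipped <- data.frame(pfam = character(), reason = character())
  for (pf in sort(unique(long$pfam))) {
    val <- unique(long$id[long$pfam == pf])
    if (length(val) == 0L) {
      skipped <- rbind(skipped, data.frame(pfam = pf, reason = "empty"))
    } else if (length(val) == length(ids)) {
      skipped <- rbind(skipped,
                       data.frame(pfam = pf, reason = "covers whole dataset"))
    } else {
      splits[[pf]] <- splitAssignment(train = setdiff(ids, val),
                                      validation = val,
                                      strategy = paste0("pfam:", pf))
    }
  }
  attr(splits, "skipped") <- skipped
  splits
}

# top-level EC class: the leading integer of an "a.b.c.d" code (truncated
# codes like "3.2.1.-" or bare "3" are fine)
.ecTopClass <- function(codes, id) {
  m <- regmatches(codes, regexpr("^[0-9]+", trimws(codes)))
  if (length(m) != length(codes) || any(!nzchar(m)))
    stop(sprintf("unparseable EC code for id %s: %s", id,
                 paste(codes, collapse = ", ")))
  as.integer(m)
}

#' EC-class split: hydrolase folds vs non-hydrolase training set
#'
#' Enzymes whose EC annotations are all hydrolase codes (top-level class 3)
#' are partitioned into \code{nFolds} near-equal cross-validation folds;
#' enzymes with only non-hydrolase classes form a single training set;
#' bifunctional enzymes carrying both a hydrolase and a non-hydrolase code
#' are discarded, as are unannotated records. Hydrolase-specific models are
#' cross-validated over the folds; non-hydrolase-specific models train on
#' the non-hydrolase set and validate on each hydrolase fold.
#'
#' @param dataset a \linkS4class{CuratedDataset}.
#' @param ecAnnotations named list mapping id to EC code strings; defaults
#'   to the dataset's \code{ec} annotation column.
#' @param nFolds number of hydrolase folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @return a \linkS4class{SplitAssignment}: \code{trainIds} = non-hydrolase
#'   training set, \code{validationIds} = all hydrolase ids,
#'   \code{validationFolds} = the folds, \code{discardedIds} = bifunctional
#'   plus unannotated ids.
#' @export
ecSplit <- function(dataset, ecAnnotations = NULL, nFolds = 5L, seed = 1L) {
  if (is.null(ecAnnotations))
    ecAnnotations <- datasetAnnotations(dataset, "ec")
  if (is.null(ecAnnotations) || !length(ecAnnotations))
    stop("no EC annotations available")
  ids <- datasetIds(dataset)
  ann <- ecAnnotations[names(ecAnnotations) %in% ids]
  ann <- ann[lengths(ann) > 0L]
  classes <- mapply(.ecTopClass, ann, names(ann), SIMPLIFY = FALSE)
  hasHydro <- vapply(classes, function(z) any(z == 3L), TRUE)
  hasOther <- vapply(classes, function(z) any(z != 3L), TRUE)
  hydro <- names(ann)[hasHydro & !hasOther]
  nonHydro <- names(ann)[!hasHydro]
  bifunctional <- names(ann)[hasHydro & hasOther]
  unannotated <- setdiff(ids, names(ann))
  nFolds <- as.integer(nFolds)
  if (length(hydro) < nFolds)
    stop(sprintf("only %d hydrolase ids for %d folds", length(hydro), nFolds))
  shuffled <- withr::with_seed(as.integer(seed), sample(hydro))
  folds <- split(shuffled, rep_len(seq_len(nFolds), length(shuffled)))
  names(folds) <- NULL
  splitAssignment(train = nonHydro, validation = hydro,
                  folds = folds,
                  discarded = c(bifunctional, unannotated),
                  strategy = "ec")
}

#' Homology-guarded training enrichment
#'
#' Adds new sequences to an existing split's training side while leaving the
#' validation side untouched. In homology mode a new id is admitted only if
#' its distance to every validation id exceeds \code{eps}, so enrichment can
#' never reintroduce leakage; with \code{eps = NULL} (random-split mode) all
#' new ids are admitted.
#'
#' @param split an existing \linkS4class{SplitAssignment}.
#' @param newIds character ids (or a \linkS4class{CuratedDataset}) to add;
#'   must be disjoint from every id already in the split.
#' @param distanceToValidation either a numeric matrix with new ids as rows
#'   and validation ids as columns, or a function
#'   \code{(newId, validationId) -> distance}. Required unless
#'   \code{eps = NULL}.
#' @param eps exclusion radius; a new id within \code{eps} of any
#'   validation id is rejected. \code{NULL} disables the guard.
#' @return the enriched \linkS4class{SplitAssignment}; rejected ids in
#'   \code{attr(x, "rejected")}.
#' @export
enrichTraining <- function(split, newIds, distanceToValidation = NULL,
                           eps = NULL) {
  if (is(newIds, "CuratedDataset")) newIds <- datasetIds(newIds)
  newIds <- as.character(newIds)
  existing <- c(trainIds(split), validationIds(split), discardedIds(split))
  clash <- intersect(newIds, existing)
  if (length(clash))
    stop("new ids collide with existing split ids: ",
         paste(clash, collapse = ", "))
  val <- validationIds(split)
  if (is.null(eps)) {
    admitted <- newIds
  } else {
    if (is.null(distanceToValidation))
      stop("distanceToValidation is required when eps is set")
    dmin <- if (is.function(distanceToValidation)) {
      vapply(newIds, function(nid)
        min(vapply(val, function(v) distanceToValidation(nid, v), 0)), 0)
    } else {
      m <- distanceToValidation
      if (!all(newIds %in% rownames(m)) || !all(val %in% colnames(m)))
        stop("distance matrix must cover all new and validation ids")
      apply(m[newIds, val, drop = FALSE], 1L, min)
    }
    admitted <- newIds[dmin > eps]
  }
  out <- splitAssignment(train = c(trainIds(split), admitted),
                         validation = val, folds = validationFolds(split),
                         discarded = discardedIds(split),
                         strategy = paste0(split@strategy, "+enriched"))
  attr(out, "rejected") <- setdiff(newIds, admitted)
  out
}
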