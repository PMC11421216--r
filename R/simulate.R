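# Synthetic protein families with known optimal-pH labels. Sequence space
# is organised in families (point-mutant radiations of random seeds) because
# every splitting strategy in the pipeline exists to cope with exactly that
# structure; labels are family base values plus per-measurement noise, with
# most families concentrated near neutral pH as in real curated sets.

#' Build a simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' test-suite: 20 families of 25 members, 120-residue seeds, 5\% per-residue
#' substitution rate, family base pH uniform on [3, 11] but drawn from
#' [6, 8] for 56\% of families, and two measurements per record with 0.3 pH
#' units of noise, a fifth of them emitted as ranges.
#'
#' @param nFamilies number of families.
#' @param membersPerFamily members per family (scalar or \code{c(lo, hi)}
#'   range).
#' @param seedLength seed sequence length in residues.
#' @param mutationRate per-residue substitution probability.
#' @param phRange support of non-neutral family base pH.
#' @param neutralFraction probability a family's base pH is drawn from
#'   [6, 8].
#' @param labelNoiseSd Gaussian noise sd per measurement (pH units).
#' @param measurementsPerRecord observations per record (scalar or range).
#' @param rangeFraction fraction of observations emitted as (v - 0.2,
#'   v + 0.2) ranges.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nFamilies = 20L, membersPerFamily = 25L,
                             seedLength = 120L, mutationRate = 0.05,
                             phRange = c(3, 11), neutralFraction = 0.56,
                             labelNoiseSd = 0.3, measurementsPerRecord = 2L,
                             rangeFraction = 0.2, seed = 1L) {
  new("SimulationConfig", nFamilies = as.integer(nFamilies),
      membersPerFamily = as.integer(membersPerFamily),
      seedLength = as.integer(seedLength),
      mutationRate = as.numeric(mutationRate),
      phRange = as.numeric(phRange),
      neutralFraction = as.numeric(neutralFraction),
      labelNoiseSd = as.numeric(labelNoiseSd),
      measurementsPerRecord = as.integer(measurementsPerRecord),
      rangeFraction = as.numeric(rangeFraction), seed = as.integer(seed))
}

.drawCount <- function(range, n) {
  if (length(range) == 1L) rep(range, n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate a protein family dataset
#'
#' Per family: a uniform-random seed sequence over the canonical alphabet;
#' members are independent point mutants (substitutions only, no indels, so
#' within-family identity stays analyzable); a base pH drawn from [6, 8]
#' with probability \code{neutralFraction} and from \code{phRange}
#' otherwise. Every record receives repeated measurements equal to the base
#' plus Gaussian noise (clamped to [0, 14]), a configured fraction emitted
#' as (v - 0.2, v + 0.2) ranges. Fake annotations: the PFAM accession
#' encodes the family, a randomly chosen half of the families carry
#' hydrolase EC codes (class 3) and the rest non-hydrolase codes, and each
#' family gets a superkingdom. Fully deterministic per seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{records} (annotated \code{AAStringSet}),
#'   \code{measurements} (raw measurement data.frame, see
#'   \code{\link{measurementTable}}) and \code{truth} (data.frame: id,
#'   family, phTrue).
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withr::with_seed(config@seed, {
    nf <- config@nFamilies
    members <- .drawCount(config@membersPerFamily, nf)
    neutral <- runif(nf) < config@neutralFraction
    basePh <- ifelse(neutral, runif(nf, 6, 8),
                     runif(nf, config@phRange[1], config@phRange[2]))
    hydroFam <- sample(nf, floor(nf / 2))
    kingdoms <- sample(c("Bacteria", "Eukaryota", "Archaea"), nf,
                       replace = TRUE)
    ids <- character(); seqs <- character()
    fam <- integer(); phTrue <- numeric()
    mRows <- vector("list", nf)
    for (f in seq_len(nf)) {
      seedSeq <- sample(CANONICAL_AA, config@seedLength, replace = TRUE)
      for (m in seq_len(members[f])) {
        s <- seedSeq
        mut <- runif(config@seedLength) < config@mutationRate
        if (any(mut))
          s[mut] <- vapply(s[mut], function(res)
            sample(setdiff(CANONICAL_AA, res), 1L), "")
        id <- sprintf("F%02dM%02d", f, m)
        ids <- c(ids, id); seqs <- c(seqs, paste(s, collapse = ""))
        fam <- c(fam, f); phTrue <- c(phTrue, basePh[f])
      }
    }
    nMeas <- .drawCount(config@measurementsPerRecord, length(ids))
    mRows <- lapply(seq_along(ids), function(i) {
      v <- basePh[fam[i]] + rnorm(nMeas[i], 0, config@labelNoiseSd)
      v <- pmin(pmax(v, 0.2), 13.8)
      isRange <- runif(nMeas[i]) < config@rangeFraction
      data.frame(id = ids[i],
                 ph = ifelse(isRange, NA_real_, v),
                 ph_lo = ifelse(isRange, v - 0.2, NA_real_),
                 ph_hi = ifelse(isRange, v + 0.2, NA_real_),
                 organism = NA_character_)
    })
    records <- Biostrings::AAStringSet(setNames(seqs, ids))
    S4Vectors::mcols(records) <- S4Vectors::DataFrame(
      pfam = sprintf("PF%05d", fam),
      ec = ifelse(fam %in% hydroFam,
                  sprintf("3.2.1.%d", fam), sprintf("1.1.1.%d", fam)),
      superkingdom = kingdoms[fam])
    list(records = records,
         measurements = measurementTable(do.call(rbind, mRows)),
         truth = data.frame(id = ids, family = fam, phTrue = phTrue))
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the FASTA, measurement table, annotation tables and truth table of
#' a simulation into a directory.
#'
#' @param sim result of \code{\link{simulateDataset}}.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
writeSimulatedDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             measurements = file.path(dir, "measurements.tsv"),
             pfam = file.path(dir, "pfam.tsv"),
             ec = file.path(dir, "ec.tsv"),
             superkingdom = file.path(dir, "superkingdom.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeFastaProteins(sim$records, paths["fasta"])
  utils::write.table(sim$measurements, paths["measurements"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  mc <- S4Vectors::mcols(sim$records)
  for (col in c("pfam", "ec", "superkingdom")) {
    df <- data.frame(id = names(sim$records),
                     value = as.character(mc[[col]]))
    names(df) <- c("id", col)
    utils::write.table(df, paths[col], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
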