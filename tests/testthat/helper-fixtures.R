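# Shared fixtures and independent oracles. Every oracle here is implemented
# from the definition it checks, not by calling the code under test.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomSeqs <- function(n, len, seed, alphabet = AA20) {
  withr::with_seed(seed, {
    s <- vapply(seq_len(n), function(i)
      paste(sample(alphabet, len, replace = TRUE), collapse = ""), "")
    setNames(s, sprintf("s%03d", seq_len(n)))
  })
}

tinyDataset <- function() {
  curatedDataset(
    c(p1 = "MKVLAA", p2 = "MKVLAC", p3 = "WWGGHH", p4 = "WWGGHY"),
    c(p1 = 4.0, p2 = 4.4, p3 = 9.0, p4 = 8.6))
}

# recursive longest-common-subsequence (exponential; tiny inputs only) --
# the brute-force oracle for the identity aligner
lcsBrute <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0L)
  a1 <- substring(a, 1, 1); b1 <- substring(b, 1, 1)
  ar <- substring(a, 2); br <- substring(b, 2)
  if (a1 == b1) return(1L + lcsBrute(ar, br))
  max(lcsBrute(a, br), lcsBrute(ar, b))
}

# identity count via the established aligner with the same scoring scheme
biostringsIdentity <- function(a, b) {
  letters <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
  sub <- diag(1, length(letters))
  dimnames(sub) <- list(letters, letters)
  as.integer(Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = sub, gapOpening = 0, gapExtension = 0,
    type = "global", scoreOnly = TRUE))
}

# union-find connected components of the eps-threshold graph
unionFindComponents <- function(D, eps) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    if (D[i, j] <= eps) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# Eq-style closed form of the rank correlation (tie-free vectors only)
closedFormSpearman <- function(yTrue, yPred) {
  n <- length(yTrue)
  d <- rank(yTrue) - rank(yPred)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# explicit sparse dot product (P . T) / N over the materialized vocabulary
bruteKmerPredict <- function(tab, query, column = "mean") {
  k <- kmerSize(tab)
  vocab <- kmerEntries(tab)$kmer
  Tvec <- kmerEntries(tab)[[column]]
  L <- nchar(query)
  occ <- substring(query, seq_len(L - k + 1), k:L)
  P <- vapply(vocab, function(km) sum(occ == km), 0)
  sum(P * Tvec) / (L - k + 1)
}

randomDistanceMatrix <- function(n, seed) {
  withr::with_seed(seed, {
    D <- matrix(runif(n * n), n, n)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    dimnames(D) <- list(sprintf("d%02d", 1:n), sprintf("d%02d", 1:n))
    D
  })
}

smallSimulation <- function(seed = 7L, ...) {
  simulateDataset(simulationConfig(nFamilies = 6L, membersPerFamily = 8L,
                                   seedLength = 60L, seed = seed, ...))
}
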