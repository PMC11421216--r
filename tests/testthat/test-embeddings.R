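test_that("truncation keeps the first residues only", {
  long <- paste(rep("A", 6000), collapse = "")
  out <- truncateSequence(c(a = long, b = "MKV"), maxLength = 5000)
  expect_equal(nchar(out[["a"]]), 5000L)
  expect_equal(out[["b"]], "MKV")
  expect_equal(attr(out, "nTruncated"), 1L)
  expect_equal(nchar(truncateSequence("MKV", maxLength = 1)), 1L)
  set <- Biostrings::AAStringSet(c(x = long))
  expect_equal(Biostrings::width(truncateSequence(set, 5000)), 5000L)
})

test_that("one-hot embedding averages position indicators", {
  v <- onehotEmbed("AA")
  expect_equal(unname(v["A"]), 1.0)
  expect_equal(sum(v), 1.0)
  v <- onehotEmbed("AC")
  expect_equal(unname(v[c("A", "C")]), c(0.5, 0.5))
  # noncanonical residues contribute zero rows but count in the denominator
  v <- onehotEmbed("AX")
  expect_equal(unname(v["A"]), 0.5)
  expect_equal(sum(v), 0.5)
  # optional 21st channel collects the unknowns instead
  v21 <- onehotEmbed("AX", unknownChannel = TRUE)
  expect_length(v21, 21L)
  expect_equal(sum(v21), 1.0)
  expect_error(onehotEmbed(""), "nonempty")
})

test_that("one-hot embedding is a composition: order-invariant, bounded", {
  withr::with_seed(13, {
    for (i in 1:10) {
      s <- paste(sample(c(AA20, "X"), 40, TRUE), collapse = "")
      shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
      expect_equal(onehotEmbed(s), onehotEmbed(shuffled))
      v <- onehotEmbed(s)
      expect_true(all(v >= 0 & v <= 1))
      canonical <- mean(strsplit(s, "")[[1]] %in% AA20)
      expect_equal(sum(v), canonical)
    }
  })
})

test_that("dataset embedding has the shape contract and is deterministic", {
  seqs <- Biostrings::AAStringSet(randomSeqs(3, 25, seed = 2))
  X <- embedDataset(seqs)
  expect_equal(dim(X), c(3L, 20L))
  expect_identical(rownames(X), names(seqs))
  expect_identical(attr(X, "embedder"), "onehot")
  expect_identical(X, embedDataset(seqs))
})

test_that("the embedding cache is reused only when ids and embedder match", {
  seqs <- Biostrings::AAStringSet(randomSeqs(4, 20, seed = 3))
  calls <- 0L
  counting <- customEmbedder("counting", d = 2L, function(sequence, id) {
    calls <<- calls + 1L
    c(nchar(sequence), 1)
  })
  f <- withr::local_tempfile(fileext = ".tsv")
  X1 <- embedDataset(seqs, counting, cachePath = f)
  expect_equal(calls, 4L)
  X2 <- embedDataset(seqs, counting, cachePath = f)
  expect_equal(calls, 4L)  # warm cache: no recompute
  expect_equal(X2, X1, tolerance = 1e-12)
  # different record set invalidates the cache
  embedDataset(seqs[1:2], counting, cachePath = f)
  expect_equal(calls, 6L)
  # different embedder name invalidates it too
  other <- customEmbedder("other", d = 2L,
                          function(sequence, id) c(0, nchar(sequence)))
  X3 <- embedDataset(seqs[1:2], other, cachePath = f)
  expect_equal(unname(X3[1, 1]), 0)
})

test_that("adapter contract violations are reported clearly", {
  seqs <- Biostrings::AAStringSet(c(a = "MKV"))
  bad <- customEmbedder("bad", d = 3L, function(sequence, id) c(1, 2))
  expect_error(embedDataset(seqs, bad), "length 2.*expected 3")
  nonfinite <- customEmbedder("nan", d = 2L,
                              function(sequence, id) c(NaN, 1))
  expect_error(embedDataset(seqs, nonfinite), "non-finite")
})

test_that("precomputed embeddings import by id and round-trip", {
  X <- matrix(rnorm(6), 3, 2,
              dimnames = list(c("a", "b", "c"), NULL))
  attr(X, "embedder") <- "esm2_meanpool"
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEmbeddingMatrix(X, f)
  back <- readEmbeddingMatrix(f)
  expect_equal(unclass(back)[, ], unclass(X)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(attr(back, "embedder"), "esm2_meanpool")

  spec <- importEmbedder(f, name = "esm2_meanpool")
  seqs <- Biostrings::AAStringSet(c(b = "MKV", a = "WWW"))
  Y <- embedDataset(seqs, spec)
  expect_equal(unname(Y["a", ]), unname(X["a", ]), tolerance = 1e-12)
  missing <- Biostrings::AAStringSet(c(zz = "MKV"))
  expect_error(embedDataset(missing, spec), "no precomputed embedding")
})
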