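test_that("table building aggregates labels per k-mer", {
  ds <- curatedDataset(c(s1 = "AAA"), c(s1 = 6.0))
  tab <- buildKmerTable(ds, k = 2)
  e <- kmerEntries(tab)
  expect_identical(e$kmer, "AA")
  expect_equal(e[e$kmer == "AA", c("mean", "min", "max")],
               data.frame(mean = 6, min = 6, max = 6), ignore_attr = TRUE)
  expect_equal(e$count, 2L)  # two occurrences in AAA

  ds <- curatedDataset(c(s1 = "AAC", s2 = "CAA"), c(s1 = 4.0, s2 = 8.0))
  e <- kmerEntries(buildKmerTable(ds, k = 2))
  aa <- e[e$kmer == "AA", ]
  expect_equal(aa$mean, 6.0)
  expect_equal(aa$min, 4.0)
  expect_equal(aa$max, 8.0)

  # sequences shorter than k are skipped with a warning
  ds <- curatedDataset(c(s1 = "MK"), c(s1 = 7.0))
  expect_warning(tab <- buildKmerTable(ds, k = 3), "skipped")
  expect_equal(nrow(kmerEntries(tab)), 0L)
  expect_equal(tab@skipped, 1L)
})

test_that("set mode counts one label copy per distinct k-mer per sequence", {
  ds <- curatedDataset(c(s1 = "AAAA"), c(s1 = 6.0))
  expect_equal(kmerEntries(buildKmerTable(ds, k = 2))$count, 3L)
  expect_equal(kmerEntries(buildKmerTable(ds, k = 2,
                                          multiset = FALSE))$count, 1L)
})

test_that("literal predictions equal the sparse dot product", {
  ds <- curatedDataset(c(s1 = "AAAA"), c(s1 = 6.0))
  tab <- buildKmerTable(ds, k = 2)
  expect_equal(as.numeric(predictKmerPh(tab, "AAAA", "literal")), 6.0)
  # AAGG: occurrences AA, AG, GG; only AA known -> (6 + 0 + 0) / 3
  expect_equal(as.numeric(predictKmerPh(tab, "AAGG", "literal")), 2.0)
  expect_equal(as.numeric(predictKmerPh(tab, "AAGG", "present_only")), 6.0)
  expect_error(predictKmerPh(tab, "A"), "shorter than k")
})

test_that("literal mode equals the materialized (P.T)/N oracle", {
  withr::with_seed(31, {
    for (k in 1:3) {
      alphabet <- AA20[1:5]
      n <- 6
      seqs <- randomSeqs(n, 12, seed = k * 17, alphabet = alphabet)
      ds <- curatedDataset(seqs, setNames(round(runif(n, 3, 11), 2),
                                          names(seqs)))
      tab <- buildKmerTable(ds, k = k)
      query <- paste(sample(alphabet, 15, TRUE), collapse = "")
      expect_equal(as.numeric(predictKmerPh(tab, query, "literal")),
                   bruteKmerPredict(tab, query), tolerance = 1e-12)
    }
  })
})

test_that("fallback to the training median is flagged", {
  ds <- curatedDataset(c(s1 = "AACA", s2 = "CCAC"), c(s1 = 5, s2 = 9))
  tab <- buildKmerTable(ds, k = 2)
  p <- predictKmerPh(tab, c(q1 = "WWWW", q2 = "AACC"), "present_only")
  expect_equal(unname(p["q1"]), trainMedian(tab))
  expect_identical(attr(p, "fallback"), c(q1 = TRUE, q2 = FALSE))
})

test_that("range predictions bracket the point prediction", {
  ds <- curatedDataset(c(s1 = "AAC", s2 = "CAA", s3 = "ACA"),
                       c(s1 = 5, s2 = 7, s3 = 6))
  tab <- buildKmerTable(ds, k = 2)
  r <- predictKmerRange(tab, "AACA", "present_only")
  p <- predictKmerPh(tab, "AACA", "present_only")
  expect_lte(r[1, "lo"], unname(p))
  expect_gte(r[1, "hi"], unname(p))
  # single-entry table: range is that entry's (min, max)
  one <- curatedDataset(c(s1 = "AAA"), c(s1 = 6))
  t1 <- buildKmerTable(one, k = 2)
  t1@entries$min <- 5; t1@entries$max <- 7
  expect_equal(unname(predictKmerRange(t1, "AAA", "present_only")[1, ]),
               c(5, 7))
  # zero table hits: degenerate median range, flagged
  r0 <- predictKmerRange(tab, "WWWW", "present_only")
  expect_equal(unname(r0[1, ]), rep(trainMedian(tab), 2))
  expect_true(attr(r0, "fallback")[1])
})

test_that("present-only predictions are convex in the training labels", {
  withr::with_seed(41, {
    seqs <- randomSeqs(10, 20, seed = 8)
    y <- setNames(runif(10, 3, 11), names(seqs))
    tab <- buildKmerTable(curatedDataset(seqs, y), k = 3)
    queries <- randomSeqs(5, 25, seed = 9)
    p <- predictKmerPh(tab, queries, "present_only")
    expect_true(all(p >= min(y) - 1e-9 & p <= max(y) + 1e-9))
  })
})

test_that("a sequence with private k-mers is predicted at its own label", {
  # s2's k-mers (over W, Y only) occur in no other training sequence
  ds <- curatedDataset(c(s1 = "AACCA", s2 = "WYWYW"), c(s1 = 5, s2 = 8.3))
  tab <- buildKmerTable(ds, k = 2)
  expect_equal(as.numeric(predictKmerPh(tab, "WYWYW", "literal")), 8.3)
  expect_equal(as.numeric(predictKmerPh(tab, "WYWYW", "present_only")), 8.3)
})

test_that("table building is order-invariant and round-trips to disk", {
  seqs <- randomSeqs(6, 15, seed = 10)
  y <- setNames(runif(6, 4, 9), names(seqs))
  t1 <- buildKmerTable(curatedDataset(seqs, y), k = 3)
  perm <- c(4, 2, 6, 1, 5, 3)
  t2 <- buildKmerTable(curatedDataset(seqs[perm], y[perm]), k = 3)
  expect_equal(kmerEntries(t1), kmerEntries(t2))
  expect_equal(trainMedian(t1), trainMedian(t2))

  f <- withr::local_tempfile(fileext = ".tsv")
  writeKmerTable(t1, f)
  back <- readKmerTable(f)
  expect_equal(kmerEntries(back), kmerEntries(t1), tolerance = 1e-12)
  expect_equal(trainMedian(back), trainMedian(t1))
  expect_identical(kmerSize(back), kmerSize(t1))
})
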