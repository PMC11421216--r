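test_that("random splits respect the ratio and the seed", {
  seqs <- randomSeqs(8, 20, seed = 1)
  ds <- curatedDataset(seqs, setNames(runif(8, 4, 9), names(seqs)))
  sp <- randomSplit(ds, validationFraction = 0.25, seed = 5L)
  expect_length(validationIds(sp), 2L)
  expect_length(trainIds(sp), 6L)
  expect_identical(validationIds(randomSplit(ds, seed = 5L)),
                   validationIds(sp))
  expect_setequal(c(trainIds(sp), validationIds(sp)), datasetIds(ds))

  seqs <- randomSeqs(100, 10, seed = 2)
  ds <- curatedDataset(seqs, setNames(runif(100, 4, 9), names(seqs)))
  sp <- randomSplit(ds, 0.25, seed = 1L)
  expect_length(validationIds(sp), 25L)
  expect_error(randomSplit(ds, 1.2), "validationFraction")
})

test_that("PFAM hold-out puts each family wholly in validation", {
  seqs <- randomSeqs(4, 15, seed = 3)
  names(seqs) <- c("r1", "r2", "r3", "r4")
  ds <- curatedDataset(seqs, setNames(c(5, 6, 7, 8), names(seqs)))
  ann <- list(r1 = c("P1"), r2 = c("P1"), r3 = c("P2"))  # r4 unannotated
  splits <- pfamHoldoutSplits(ds, ann)
  expect_setequal(names(splits), c("P1", "P2"))
  expect_setequal(validationIds(splits$P1), c("r1", "r2"))
  expect_setequal(trainIds(splits$P1), c("r3", "r4"))
  # unannotated records train in every split
  expect_true(all(vapply(splits, function(s) "r4" %in% trainIds(s), TRUE)))

  # an accession covering everything is skipped and reported
  annAll <- list(r1 = "PX", r2 = "PX", r3 = "PX", r4 = "PX")
  skipped <- pfamHoldoutSplits(ds, annAll)
  expect_length(skipped, 0L)
  expect_identical(attr(skipped, "skipped")$pfam, "PX")
})

test_that("EC split separates hydrolases, discards bifunctionals", {
  seqs <- randomSeqs(12, 15, seed = 4)
  ids <- names(seqs)
  ds <- curatedDataset(seqs, setNames(runif(12, 4, 9), ids))
  ann <- c(
    setNames(lapply(1:6, function(i) sprintf("3.2.1.%d", i)), ids[1:6]),
    list(), # ids[7:9] non-hydrolase, ids[10] bifunctional, ids[11] truncated
    setNames(list("1.1.1.194", "2.7.7.7", "6.3.2.1"), ids[7:9]),
    setNames(list(c("3.5.1.10", "1.5.1.5")), ids[10]),
    setNames(list("3.2.1.-"), ids[11]))
  # ids[12] unannotated
  sp <- ecSplit(ds, ann, nFolds = 3L, seed = 2L)
  expect_setequal(validationIds(sp), c(ids[1:6], ids[11]))
  expect_setequal(trainIds(sp), ids[7:9])
  expect_setequal(discardedIds(sp), ids[c(10, 12)])
  expect_length(validationFolds(sp), 3L)
  sizes <- lengths(validationFolds(sp))
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_setequal(unlist(validationFolds(sp)), validationIds(sp))
  # full coverage: every id lands in exactly one of the three groups
  expect_setequal(c(trainIds(sp), validationIds(sp), discardedIds(sp)),
                  datasetIds(ds))

  expect_error(ecSplit(ds, setNames(list("EC?"), ids[1])), "unparseable")
})

test_that("enrichment guards the validation neighborhood", {
  sp <- splitAssignment(train = c("t1", "t2"), validation = c("v1", "v2"))
  dist <- matrix(c(0.5, 0.9, 0.9, 0.9), 2, 2,
                 dimnames = list(c("n1", "n2"), c("v1", "v2")))
  out <- enrichTraining(sp, c("n1", "n2"), dist, eps = 0.6)
  expect_setequal(trainIds(out), c("t1", "t2", "n2"))     # n1 too close
  expect_identical(attr(out, "rejected"), "n1")
  expect_identical(validationIds(out), validationIds(sp))

  # function-valued distances work too
  out2 <- enrichTraining(sp, c("n1", "n2"),
                         function(a, b) dist[a, b], eps = 0.6)
  expect_setequal(trainIds(out2), trainIds(out))

  # random mode: no guard, everything joins
  all <- enrichTraining(sp, c("n1", "n2"), eps = NULL)
  expect_setequal(trainIds(all), c("t1", "t2", "n1", "n2"))

  expect_error(enrichTraining(sp, "v1", eps = NULL), "collide")
})
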