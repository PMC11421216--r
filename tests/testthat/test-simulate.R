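test_that("simulation produces the configured counts and annotations", {
  sim <- simulateDataset(simulationConfig(nFamilies = 5, membersPerFamily = 10,
                                          seedLength = 50, seed = 2))
  expect_length(sim$records, 50L)
  mc <- S4Vectors::mcols(sim$records)
  expect_length(unique(mc$pfam), 5L)
  expect_setequal(unique(sim$truth$family), 1:5)
  # half the families (rounded down) carry hydrolase EC codes
  topClass <- as.integer(sub("\\..*", "", mc$ec))
  famClass <- tapply(topClass, sim$truth$family, unique)
  expect_equal(sum(famClass == 3L), 2L)
  expect_true(all(mc$superkingdom %in% c("Bacteria", "Eukaryota", "Archaea")))
  # measurements validate and reference known ids
  expect_true(all(sim$measurements$id %in% names(sim$records)))
})

test_that("zero mutation rate gives identical family members", {
  sim <- simulateDataset(simulationConfig(nFamilies = 3, membersPerFamily = 4,
                                          seedLength = 40, mutationRate = 0,
                                          seed = 3))
  S <- pairwiseSimilarity(sim$records)
  fam <- setNames(sim$truth$family, sim$truth$id)
  within <- outer(fam, fam, "==")
  diag(within) <- FALSE
  expect_true(all(S[within] == 1))
})

test_that("the generator is byte-deterministic per seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- writeSimulatedDataset(simulateDataset(simulationConfig(
    nFamilies = 4, membersPerFamily = 5, seedLength = 30, seed = 11)), d1)
  p2 <- writeSimulatedDataset(simulateDataset(simulationConfig(
    nFamilies = 4, membersPerFamily = 5, seedLength = 30, seed = 11)), d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  # a different seed changes the sequences
  p3 <- simulateDataset(simulationConfig(nFamilies = 4, membersPerFamily = 5,
                                         seedLength = 30, seed = 12))
  expect_false(identical(as.character(p3$records),
                         as.character(simulateDataset(simulationConfig(
                           nFamilies = 4, membersPerFamily = 5,
                           seedLength = 30, seed = 11))$records)))
})

test_that("within-family distances are below between-family distances", {
  sim <- smallSimulation(seed = 5L)
  S <- pairwiseSimilarity(sim$records)
  D <- similarityToDistance(S)
  fam <- setNames(sim$truth$family, sim$truth$id)
  same <- outer(fam, fam, "==")
  diag(same) <- NA
  expect_gt(min(D[!same], na.rm = TRUE), max(D[same], na.rm = TRUE))
  # density clustering at a mid eps recovers the planted families exactly
  cl <- clusterIndices(densityCluster(D, eps = 0.4, minSamples = 1L))
  expect_identical(outer(cl, cl, "=="), same | is.na(same))
})

test_that("the neutral-label fraction tracks its configuration", {
  sim <- simulateDataset(simulationConfig(nFamilies = 120,
                                          membersPerFamily = 1,
                                          seedLength = 10,
                                          neutralFraction = 0.56, seed = 8))
  frac <- mean(sim$truth$phTrue >= 6 & sim$truth$phTrue <= 8)
  # 120 Bernoulli families; allow ~3 binomial sds around the target
  # (plus the U[3,11] families that land in [6,8] by chance, ~25%)
  expected <- 0.56 + 0.44 * 0.25
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / 120))
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(mutationRate = 1.5), "mutationRate")
  expect_error(simulationConfig(phRange = c(9, 3)), "phRange")
  expect_error(simulationConfig(neutralFraction = -0.1), "neutralFraction")
})
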