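# the peptide-level generator: determinism, ground-truth bookkeeping,
# left-censored missingness

test_that("identical parameters and seed reproduce the dataset exactly", {
  p <- simulationParams(nProteins = 60)
  a <- simulateDataset(p, seed = 11)
  b <- simulateDataset(p, seed = 11)
  expect_identical(assay(a$peptides, "intensity"),
                   assay(b$peptides, "intensity"))
  expect_identical(a$truth$proteins, b$truth$proteins)
  expect_identical(a$truth$censored, b$truth$censored)
  c <- simulateDataset(p, seed = 12)
  expect_false(identical(assay(a$peptides, "intensity"),
                         assay(c$peptides, "intensity")))
})

test_that("fracRegulated = 0 gives an all-zero fold-change table", {
  sim <- simulateDataset(simulationParams(nProteins = 80, fracRegulated = 0),
                         seed = 2)
  lfc <- as.matrix(sim$truth$proteins[, grep("^lfc_",
                                             colnames(sim$truth$proteins))])
  expect_true(all(lfc == 0))
  expect_false(any(sim$truth$proteins$regulated))
})

test_that("disabling censoring yields a complete matrix", {
  sim <- simulateDataset(simulationParams(nProteins = 50,
                                          censorMidpoint = -Inf), seed = 3)
  expect_false(anyNA(assay(sim$peptides, "intensity")))
  expect_false(any(sim$truth$censored))
})

test_that("number of regulated proteins behaves binomially", {
  # Binomial(2000, 0.05): mean 100, sd 9.75; [60, 140] is ~+-4 sd
  sim <- simulateDataset(simulationParams(nProteins = 2000,
                                          fracRegulated = 0.05), seed = 1)
  nReg <- sum(sim$truth$proteins$regulated)
  expect_gte(nReg, 60)
  expect_lte(nReg, 140)
})

test_that("missingness decreases as base abundance rises", {
  rates <- vapply(c(16, 18, 20, 22), function(mu) {
    sim <- simulateDataset(simulationParams(nProteins = 150,
                                            baseAbundanceMean = mu),
                           seed = 5)
    mean(is.na(assay(sim$peptides, "intensity")))
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_gt(rates[1], rates[4])
})

test_that("unregulated proteins are balanced across conditions", {
  sim <- simulateDataset(simulationParams(nProteins = 1000,
                                          fracRegulated = 0), seed = 9)
  x <- log2(assay(sim$peptides, "intensity"))
  cond <- sampleDesign(sim$peptides)$condition
  byCond <- lapply(unique(cond), function(cc) {
    v <- x[, cond == cc, drop = FALSE]
    v[!is.na(v)]
  })
  means <- vapply(byCond, mean, numeric(1))
  se <- sqrt(sum(vapply(byCond, function(v) var(v) / length(v), numeric(1))))
  expect_lt(max(means) - min(means), 3 * se)
})

test_that("invalid parameters are rejected", {
  expect_error(simulationParams(nConditions = 1), "nConditions")
  expect_error(simulationParams(nConditions = 4), "2 or 3")
  expect_error(simulationParams(nReplicates = 1), "nReplicates")
  expect_error(simulationParams(nProteins = 0), "nProteins")
  expect_error(simulationParams(fracRegulated = 1.2), "0, 1")
  expect_error(simulationParams(censorScale = 0), "censorScale")
  expect_error(simulationParams(replicateNoiseSd = -1), "replicateNoiseSd")
})

test_that("the toy ontology is acyclic, rooted and round-trips seeds", {
  onto <- simulateOntology(25, sprintf("P%02d", 1:40), seed = 7)
  g <- onto$graph
  expect_s4_class(g, "OntologyGraph")
  expect_identical(nrow(termInfo(g)), 25L)
  # root has no parents; every other term reaches the root
  anc <- termAncestors(g)
  expect_identical(anc[[termIds(g)[1]]], character(0))
  expect_true(all(vapply(anc[-1], function(a) termIds(g)[1] %in% a,
                         logical(1))))
  onto2 <- simulateOntology(25, sprintf("P%02d", 1:40), seed = 7)
  expect_identical(onto$annotations, onto2$annotations)
})

test_that("a single-term ontology is a bare root", {
  onto <- simulateOntology(1, sprintf("P%02d", 1:10), seed = 1)
  expect_identical(nrow(termInfo(onto$graph)), 1L)
  expect_identical(nrow(onto$graph@edges), 0L)
})

test_that("planting more terms than leaves or without a significant set fails", {
  expect_error(simulateOntology(3, letters, plantedTerms = 5,
                                significantSet = letters[1:5], seed = 1),
               "plantedTerms")
  expect_error(simulateOntology(10, letters, plantedTerms = 1, seed = 1),
               "significantSet")
})
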