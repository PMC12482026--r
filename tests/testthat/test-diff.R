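# differential testing table, the two significance cascades, extreme
# candidates, imputation and volcano output

library(S4Vectors)

# hand-built three-condition result table for cascade logic
toyOverexpressionResult <- function() {
  res <- DataFrame(
    nValid_WT = c(5L, 5L, 5L, 3L, 5L),
    nValid_OE1 = c(5L, 5L, 5L, 5L, 5L),
    nValid_OE2 = c(5L, 5L, 5L, 5L, 5L),
    diff_OE1_vs_WT = c(1.5, 1.5, 0.6, 1.5, 1.5),
    q_OE1_vs_WT = c(0.001, 0.001, 0.001, 0.001, 0.5),
    diff_OE2_vs_WT = c(0.2, 0.2, 0.2, 0.2, 0.2),
    q_OE2_vs_WT = c(0.9, 0.9, 0.9, 0.9, 0.9),
    diff_OE2_vs_OE1 = c(-1.3, -1.3, -0.4, -1.3, -1.3),
    q_OE2_vs_OE1 = c(0.2, 0.2, 0.2, 0.2, 0.2),
    maxAbsDiff = c(1.5, 1.5, 0.6, 1.5, 1.5),
    anova_q = c(0.001, 0.02, 0.001, 0.001, 0.001),
    row.names = paste0("P", 1:5))
  metadata(res) <- list(conditions = c("WT", "OE1", "OE2"),
                        pairs = c("OE1_vs_WT", "OE2_vs_WT", "OE2_vs_OE1"),
                        experiment = "overexpression")
  res
}

test_that("the overexpression cascade is the stated four-way conjunction", {
  res <- toyOverexpressionResult()
  # P1 passes everything; P2 fails ANOVA q; P3 fails fold change;
  # P4 fails min valid; P5 fails every pairwise Welch q
  expect_identical(filterOverexpression(res), "P1")
  # relaxing any single criterion can only grow the set
  expect_true(all(c("P1", "P2") %in%
                  filterOverexpression(res, qThreshold = 0.05)))
  expect_true(all(c("P1", "P3") %in%
                  filterOverexpression(res, fcThreshold = 1.2)))
  expect_true(all(c("P1", "P4") %in%
                  filterOverexpression(res, minValid = 3)))
})

test_that("the knockout cascade applies strict |log2| and q thresholds", {
  res <- DataFrame(
    nValid_WT = rep(5L, 4), nValid_KO = rep(5L, 4),
    diff_KO_vs_WT = c(1.17, -0.79, 1.25617, 0.9),
    q_KO_vs_WT = c(0.002, 0.001, 0.005, 0.02),
    maxAbsDiff = abs(c(1.17, -0.79, 1.25617, 0.9)),
    row.names = paste0("P", 1:4))
  metadata(res) <- list(conditions = c("WT", "KO"), pairs = "KO_vs_WT",
                        experiment = "knockout")
  # P2: |diff| = 0.79 < 0.8 despite tiny q; P4: q above threshold
  expect_identical(filterKnockout(res), c("P1", "P3"))
})

test_that("diffTest produces a coherent table on simulated data", {
  sim <- simulateDataset(simulationParams(nProteins = 120), seed = 6)
  pq <- quantifyProteins(sim$peptides, "summed")
  res <- diffTest(pq, nPerm = 400, seed = 2)
  expect_identical(metadata(res)$experiment, "overexpression")
  expect_setequal(metadata(res)$pairs,
                  c("OE1_vs_WT", "OE2_vs_WT", "OE2_vs_OE1"))
  expect_true(all(res$nValid_WT <= 5))
  qc <- paste0("q_", metadata(res)$pairs)
  for (cn in c(qc, "anova_q"))
    expect_true(all(res[[cn]] >= 0 & res[[cn]] <= 1, na.rm = TRUE))
  # significance flag matches the cascade recomputed from the table
  expect_identical(rownames(res)[res$significant],
                   filterOverexpression(res))
  # regulated truth should be enriched among significant calls
  reg <- sim$truth$proteins$protein_group[sim$truth$proteins$regulated]
  sig <- rownames(res)[res$significant]
  if (length(sig) > 0) expect_gt(mean(sig %in% reg), 0.5)
})

test_that("extreme candidates flag dropouts and huge fold changes", {
  log2mat <- rbind(
    present = c(20, 20.1, 19.9, 20, 20.2, 21, 21.1, 20.9, 21, 21.2),
    dropout = c(NA, NA, NA, NA, NA, 18, 18.1, 17.9, 18, 18.2),
    extreme = c(14, 14.1, 13.9, 14, 14.1, 20, 20.1, 19.9, 20, 20.2))
  colnames(log2mat) <- paste0(rep(c("WT", "KO"), each = 5), "_r", 1:5)
  cond <- rep(c("WT", "KO"), each = 5)
  mk <- function(m) ProteinQuant(m, nPeptides = rep(2L, 3), condition = cond,
                                 method = "summed")
  lf <- ProteinQuant(log2mat, nPeptides = rep(2L, 3), condition = cond,
                     method = "maxlfq")
  out <- summingExtremeCandidates(lf, mk(log2mat))
  expect_setequal(out$protein_group, c("dropout", "extreme"))
  expect_identical(out$reason[out$protein_group == "dropout"], "dropout")
  expect_identical(out$reason[out$protein_group == "extreme"], "extreme_fc")
  # fully observed protein with |diff| = 1 is not a candidate
  expect_false("present" %in% out$protein_group)
})

test_that("censor-driven one-condition dropout is flagged from simulation", {
  p <- simulationParams(nConditions = 2, nProteins = 300,
                        fracRegulated = 0.08, effectSizes = 8)
  sim <- simulateDataset(p, seed = 13)
  lf <- quantifyProteins(sim$peptides, "maxlfq")
  sm <- quantifyProteins(sim$peptides, "summed")
  out <- summingExtremeCandidates(lf, sm)
  reg <- sim$truth$proteins$protein_group[sim$truth$proteins$regulated]
  expect_true(all(reg %in% out$protein_group))
})

test_that("imputation draws from the down-shifted normal, deterministically", {
  set.seed(40)
  mat <- matrix(rnorm(60 * 4, 20, 1), 60, 4,
                dimnames = list(sprintf("P%02d", 1:60), paste0("s", 1:4)))
  full <- ProteinQuant(mat, nPeptides = rep(1L, 60),
                       condition = c("A", "A", "B", "B"), method = "maxlfq")
  expect_identical(assay(imputeLeftCensored(full, seed = 1), "log2"), mat)
  mat2 <- mat
  mat2[sample(240, 50)] <- NA
  holey <- ProteinQuant(mat2, nPeptides = rep(1L, 60),
                        condition = c("A", "A", "B", "B"), method = "maxlfq")
  a <- imputeLeftCensored(holey, seed = 7)
  b <- imputeLeftCensored(holey, seed = 7)
  expect_identical(assay(a, "log2"), assay(b, "log2"))
  expect_false(anyNA(assay(a, "log2")))
  # observed cells untouched
  keep <- !is.na(mat2)
  expect_identical(assay(a, "log2")[keep], mat2[keep])
  # imputed values sit low: below each sample's observed mean
  for (s in 1:4) {
    imp <- assay(a, "log2")[is.na(mat2[, s]), s]
    expect_true(all(imp < mean(mat2[, s], na.rm = TRUE)))
  }
})

test_that("imputation refuses samples with fewer than 3 observed values", {
  mat <- cbind(c(20, NA, NA, NA), c(19, 20, 21, 22))
  colnames(mat) <- c("s1", "s2")
  rownames(mat) <- paste0("P", 1:4)
  pq <- ProteinQuant(mat, nPeptides = rep(1L, 4), condition = c("A", "B"),
                     method = "maxlfq")
  expect_warning(out <- imputeLeftCensored(pq, seed = 1), "fewer than 3")
  expect_true(anyNA(assay(out, "log2")[, "s1"]))
})

test_that("volcano table is consistent with the tests and the filter", {
  sim <- simulateDataset(simulationParams(nConditions = 2, nProteins = 150),
                         seed = 14)
  pq <- quantifyProteins(sim$peptides, "summed")
  res <- diffTest(pq, nPerm = 300, seed = 1)
  imp <- imputeLeftCensored(pq, seed = 1)
  vt <- volcanoTable(res, imp, "KO_vs_WT")
  expect_identical(vt$protein_group, rownames(res))
  # q = 1 maps to y = 0
  at1 <- which(res$q_KO_vs_WT == 1)
  if (length(at1)) expect_true(all(vt$negLog10Q[at1] == 0))
  expect_identical(vt$significant, res$significant)
  # proteins meeting the valid-value criterion keep their raw difference
  raw <- res$nValid_WT >= 4 & res$nValid_KO >= 4
  expect_equal(vt$log2diff[raw], res$diff_KO_vs_WT[raw])
  expect_true(all(vt$from_imputed == !raw))
  expect_error(volcanoTable(res, imp, "nope"), "unknown pair")
})
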