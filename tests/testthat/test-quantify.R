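# peptide-to-protein rollup: pairwise ratios, MaxLFQ least squares, summing

test_that("pairwise median log-ratios match their definition", {
  # two peptides with identical spacing
  x <- rbind(c(10, 12), c(11, 13))
  R <- pairwiseMedianLogRatios(x)
  expect_equal(R[1, 2], 2)
  expect_equal(R[2, 1], -2)
  # one peptide observed in one sample only: no pairs
  y <- matrix(c(10, NA), 1, 2)
  expect_true(all(is.na(pairwiseMedianLogRatios(y))))
  # median of ratios {1, 2, 7}
  z <- cbind(c(0, 0, 0), c(1, 2, 7))
  expect_equal(pairwiseMedianLogRatios(z)[1, 2], 2)
  # minShared excludes thin pairs
  w <- rbind(c(10, 11, NA), c(NA, 12, 13))
  expect_true(is.na(pairwiseMedianLogRatios(w, minShared = 2)[1, 2]))
  expect_error(pairwiseMedianLogRatios(x[0, , drop = FALSE]), "peptide")
})

test_that("maxLFQProfile reproduces closed-form cases", {
  # a single complete peptide is its own profile
  one <- matrix(c(10, 12, 11), 1, 3)
  expect_equal(unname(maxLFQProfile(one)), c(10, 12, 11))
  # constant peptide offset: ratios consistent, anchored at the joint mean
  two <- rbind(c(10, 12, 11), c(13, 15, 14))
  expect_equal(unname(maxLFQProfile(two)), c(11.5, 13.5, 12.5))
  # sample without data stays missing; singleton gets its own mean
  iso <- rbind(c(10, 12, NA), c(11, 13, NA))
  p <- maxLFQProfile(iso)
  expect_true(is.na(p[3]))
  expect_equal(unname(p[1:2]), c(10.5, 12.5))
})

test_that("maxLFQProfile matches the brute-force normal-equations oracle", {
  set.seed(42)
  for (i in 1:40) {
    x <- randomConnectedFixture(nPep = sample(2:8, 1),
                                nSamp = sample(3:6, 1),
                                missRate = runif(1, 0.1, 0.4))
    if (is.null(x)) next
    expect_equal(maxLFQProfile(x), oracleMaxLFQ(x), tolerance = 1e-10)
  }
})

test_that("disconnected sample groups report only the largest component", {
  # peptide 1 links samples 1-2, peptide 2 links samples 3-4-5; no overlap
  x <- rbind(c(10, 11, NA, NA, NA),
             c(NA, NA, 20, 21, 22))
  p <- maxLFQProfile(x)
  expect_true(all(is.na(p[1:2])))
  expect_equal(unname(p[3:5]), c(20, 21, 22))
})

test_that("sumQuantify is log2 of the summed linear intensities", {
  expect_equal(unname(sumQuantify(matrix(log2(c(100, 300)), 2, 1))),
               log2(400))
  one <- matrix(c(10, 12, 11), 1, 3)
  expect_equal(unname(sumQuantify(one)), c(10, 12, 11))
  gap <- rbind(c(10, NA), c(12, NA))
  expect_true(is.na(sumQuantify(gap)[2]))
})

test_that("quantifyProteins rolls up every protein with the right tags", {
  pep <- toyPeptideTable()
  m <- quantifyProteins(pep, "maxlfq")
  s <- quantifyProteins(pep, "summed")
  expect_identical(rownames(m), c("A", "B", "C"))
  expect_identical(quantMethod(m), "maxlfq")
  expect_identical(quantMethod(s), "summed")
  expect_identical(unname(nPeptides(m)), c(2L, 1L, 1L))
  # single-peptide proteins: both methods reduce to the peptide profile
  expect_equal(assay(m, "log2")["B", ], assay(s, "log2")["B", ])
  expect_equal(assay(m, "log2")["C", ], assay(s, "log2")["C", ])
})

test_that("rollup is invariant to peptide row order", {
  pep <- toyPeptideTable()
  x <- assay(pep, "intensity")
  perm <- c(3, 1, 4, 2)
  pep2 <- PeptideQuant(x[perm, ],
                       proteinGroup = rowData(pep)$protein_group[perm],
                       condition = colData(pep)$condition,
                       precursorId = rowData(pep)$precursor_id[perm])
  for (method in c("maxlfq", "summed"))
    expect_equal(assay(quantifyProteins(pep, method), "log2"),
                 assay(quantifyProteins(pep2, method), "log2"))
})

test_that("scaling one sample shifts its estimates by exactly that amount", {
  pep <- toyPeptideTable()
  x <- assay(pep, "intensity")
  x[, 2] <- x[, 2] * 2^1.5
  pep2 <- PeptideQuant(x, proteinGroup = rowData(pep)$protein_group,
                       condition = colData(pep)$condition,
                       precursorId = rowData(pep)$precursor_id)
  for (method in c("maxlfq", "summed")) {
    before <- assay(quantifyProteins(pep, method), "log2")
    after <- assay(quantifyProteins(pep2, method), "log2")
    delta <- after - before
    expect_equal(unname(delta[, 2]), rep(1.5, 3))
    expect_equal(unname(delta[, -2]), matrix(0, 3, 3))
  }
})

test_that("with consistent offsets maxlfq and summed differ by a constant", {
  set.seed(8)
  base <- rnorm(4, 20)
  x <- outer(c(0, -1, 0.5), rep(1, 4)) + rep(base, each = 3) +
    0 * rnorm(12)                      # exact offsets, complete data
  lfq <- maxLFQProfile(x)
  sm <- sumQuantify(x)
  expect_lt(diff(range(lfq - sm)), 1e-10)
})

test_that("estimated profiles track the true protein profiles", {
  p <- simulationParams(nProteins = 300, fracRegulated = 1,
                        censorMidpoint = -Inf)
  sim <- simulateDataset(p, seed = 1)
  pq <- quantifyProteins(sim$peptides, "maxlfq")
  truth <- sim$truth$proteins
  lfcCols <- grep("^lfc_", colnames(truth), value = TRUE)
  cond <- sampleDesign(sim$peptides)$condition
  est <- assay(pq, "log2")
  cors <- vapply(seq_len(nrow(truth)), function(i) {
    tp <- as.numeric(truth[i, lfcCols])[match(cond, sub("lfc_", "", lfcCols))]
    suppressWarnings(cor(est[truth$protein_group[i], ], tp))
  }, numeric(1))
  expect_gte(median(cors, na.rm = TRUE), 0.99)
})
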