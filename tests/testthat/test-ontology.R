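# identifier translation, annotation propagation, Fisher enrichment

test_that("translateIds expands one-to-many and reports unmapped ids", {
  mapping <- data.frame(from = c("U1", "U2", "U2"),
                        to = c("AT1", "AT2A", "AT2B"))
  out <- translateIds(c("U1", "U2", "U3"), mapping)
  expect_identical(out$translated$to[out$translated$from == "U1"], "AT1")
  expect_setequal(out$translated$to[out$translated$from == "U2"],
                  c("AT2A", "AT2B"))
  expect_identical(out$unmapped, "U3")
  # identity mapping is the identity
  idm <- data.frame(from = c("a", "b"), to = c("a", "b"))
  expect_identical(translateIds(c("a", "b"), idm)$translated$to, c("a", "b"))
  expect_error(translateIds("a", mapping[0, ]), "empty")
})

test_that("propagation follows the true-path rule", {
  terms <- data.frame(id = c("root", "mid", "leaf"),
                      name = c("root", "mid", "leaf"), namespace = "bp")
  edges <- data.frame(child = c("mid", "leaf"), parent = c("root", "mid"),
                      relation = "is_a")
  g <- OntologyGraph(terms, edges)
  direct <- data.frame(protein_id = "p1", term_id = "leaf")
  prop <- propagateAnnotations(direct, g)
  expect_setequal(prop$term_id, c("leaf", "mid", "root"))
  # root-only annotation is unchanged
  rootOnly <- data.frame(protein_id = "p2", term_id = "root")
  expect_identical(propagateAnnotations(rootOnly, g)$term_id, "root")
  # unknown terms are skipped with a warning
  expect_warning(
    out <- propagateAnnotations(
      data.frame(protein_id = c("p1", "p1"), term_id = c("leaf", "ghost")),
      g),
    "absent")
  expect_setequal(out$term_id, c("leaf", "mid", "root"))
})

test_that("fisherEnrichment matches the hypergeometric oracle on a toy case", {
  detected <- sprintf("p%02d", 1:10)
  significant <- detected[1:5]
  ann <- data.frame(protein_id = detected[1:2], term_id = "T1")
  out <- fisherEnrichment(significant, detected, ann, propagate = FALSE)
  # N = 10, K = 5, n = 2, k = 2: p = C(5,2)/C(10,2) = 10/45
  expect_equal(out$p, 10 / 45, tolerance = 1e-12)
  expect_equal(out$p, oracleHyperP(2, 5, 10, 2), tolerance = 1e-12)
  expect_identical(out$k, 2L)
  expect_identical(out$n, 2L)
  expect_equal(out$pct, 100)
  # a term with no significant member has one-sided p = 1
  ann0 <- data.frame(protein_id = detected[6:7], term_id = "T0")
  out0 <- fisherEnrichment(significant, detected, ann0, propagate = FALSE)
  expect_equal(out0$p, 1)
  expect_error(fisherEnrichment(c("zz"), detected, ann), "subset")
})

test_that("enrichment p equals the oracle across random tables", {
  set.seed(50)
  for (i in 1:25) {
    N <- sample(10:40, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    detected <- sprintf("p%03d", 1:N)
    significant <- detected[1:K]
    members <- sample(detected, n)
    ann <- data.frame(protein_id = members, term_id = "T")
    out <- fisherEnrichment(significant, detected, ann, propagate = FALSE)
    k <- sum(members %in% significant)
    expect_equal(out$p, oracleHyperP(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("BH q is monotone in p, never below p, and namespace-scoped", {
  onto <- simulateOntology(40, sprintf("P%03d", 1:200), plantedTerms = 2,
                           significantSet = sprintf("P%03d", 1:40), seed = 6)
  out <- fisherEnrichment(sprintf("P%03d", 1:40), sprintf("P%03d", 1:200),
                          onto$annotations, onto$graph)
  expect_true(all(out$q >= out$p - 1e-15))
  expect_true(all(diff(out$q) >= -1e-15))    # ordered by p
  expect_true(all(out$q <= 1))
  # two.sided route is a valid p as well
  out2 <- fisherEnrichment(sprintf("P%03d", 1:40), sprintf("P%03d", 1:200),
                           onto$annotations, onto$graph,
                           alternative = "two.sided")
  expect_true(all(out2$p >= 0 & out2$p <= 1))
})

test_that("planted terms carry the strongest enrichment signal", {
  hits <- 0L
  for (s in 1:10) {
    onto <- simulateOntology(60, sprintf("P%03d", 1:500), plantedTerms = 1,
                             significantSet = sprintf("P%03d", 1:50),
                             seed = s)
    enr <- fisherEnrichment(sprintf("P%03d", 1:50), sprintf("P%03d", 1:500),
                            onto$annotations, onto$graph)
    hits <- hits + (enr$term[1] == onto$planted)
  }
  expect_gte(hits, 9L)
})
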