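test_that("profile kernels reproduce hand-computed values", {
  p <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(0, 0, 1),
             z = c(0, 0, 0))
  tan <- simValues(tanimotoSimilarity(p))
  jac <- simValues(jaccardSimilarity(p))
  cos <- simValues(cosineSimilarity(p))
  # identical vectors and the diagonal
  expect_equal(unname(diag(tan)), rep(1, 4))
  # (1,1,0) vs (1,0,1): dot 1, sizes 2 -> 1/(2+2-1)
  expect_equal(tan["a", "b"], 1 / 3)
  expect_equal(jac["a", "b"], 1 / 3)
  # cosine: 1 / (sqrt(2) * sqrt(2))
  expect_equal(cos["a", "b"], 0.5)
  # disjoint supports
  expect_equal(tan["a", "c"], 0)
  expect_equal(cos["a", "c"], 0)
  # zero-profile entity scores 0 off-diagonal, 1 on the diagonal
  expect_equal(unname(tan["z", c("a", "b", "c")]), c(0, 0, 0))
  expect_equal(tan["z", "z"], 1)
})

test_that("profile kernels reject empty and non-binary input", {
  expect_error(tanimotoSimilarity(matrix(0, 0, 3)), "no entities")
  expect_error(jaccardSimilarity(rbind(a = c(0, 2))), "binary")
})

test_that("kernel outputs satisfy similarity-matrix invariants and known
           inequalities on random profiles", {
  for (seed in 1:5) {
    X <- randomProfiles(12, 20, seed)
    tan <- simValues(tanimotoSimilarity(X))
    jac <- simValues(jaccardSimilarity(X))
    cos <- simValues(cosineSimilarity(X))
    for (v in list(tan, jac, cos)) {
      expect_equal(v, t(v))
      expect_true(all(v >= 0 & v <= 1))
      expect_equal(unname(diag(v)), rep(1, nrow(v)))
    }
    # Tanimoto and Jaccard coincide on binary vectors
    expect_equal(tan, jac)
    # Jaccard <= cosine pointwise
    expect_true(all(jac <= cos + 1e-12))
  }
})

test_that("inverse shortest-path similarity follows the exponential decay
           transform on the filtered graph", {
  edges <- data.frame(from = c("a", "b", "c", "a"),
                      to   = c("b", "c", "d", "e"),
                      confidence = c(0.9, 0.8, 0.7, 0.3))
  g <- confidenceGraph(edges, nodes = c("a", "b", "c", "d", "e", "f"))
  s <- simValues(ispSimilarity(g, A = 0.9, b = 1, minConfidence = 0.5))
  expect_equal(s["a", "b"], 0.9 * exp(-1))          # adjacent, D = 1
  expect_equal(s["a", "c"], 0.9 * exp(-2))          # two hops
  expect_equal(s["a", "d"], 0.9 * exp(-3))
  expect_equal(s["a", "e"], 0)  # its only edge fell below the filter
  expect_equal(s["a", "f"], 0)  # isolated node
  expect_equal(s["a", "a"], 1)  # stored diagonal is 1 ...
  expect_equal(ispTransform(0, A = 0.9, b = 1), 0.9)  # ... raw transform is A
  # monotone non-increasing in hop distance
  expect_true(s["a", "b"] > s["a", "c"])
  expect_true(s["a", "c"] > s["a", "d"])
})

test_that("confidence-graph construction rejects inconsistent input", {
  expect_error(confidenceGraph(data.frame(from = "a", to = "b",
                                          confidence = 0.7),
                               nodes = "a"), "unknown node")
  expect_error(confidenceGraph(data.frame(from = "a", to = "a",
                                          confidence = 0.7)), "self-loops")
  expect_error(confidenceGraph(data.frame(from = "a", to = "b",
                                          confidence = 1.4)), "\\[0, 1\\]")
})

test_that("common-neighbour similarity applies binary indices to adjacency
           vectors", {
  # x's neighbours {a, b}; y's neighbours {a, c}: jaccard 1/3
  edges <- data.frame(from = c("x", "x", "y", "y"),
                      to   = c("a", "b", "a", "c"),
                      confidence = rep(0.9, 4))
  g <- confidenceGraph(edges)
  jac <- simValues(commonNeighborSimilarity(g, "jaccard"))
  expect_equal(jac["x", "y"], 1 / 3)
  # identical neighbour sets score 1; disjoint sets score 0
  edges2 <- data.frame(from = c("u", "v", "w"), to = c("a", "a", "b"),
                       confidence = rep(0.9, 3))
  jac2 <- simValues(commonNeighborSimilarity(confidenceGraph(edges2)))
  expect_equal(jac2["u", "v"], 1)
  expect_equal(jac2["u", "w"], 0)
})

test_that("alignment similarity normalises scores into [0, 1] and matches a
           hand-built dynamic-programming case", {
  sub <- matrix(-1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  diag(sub) <- 1
  seqs <- c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGA")
  loc <- simValues(alignmentSimilarity(seqs, mode = "local",
                                       substitutionMatrix = sub,
                                       gapOpening = 0, gapExtension = 1))
  expect_equal(loc["s1", "s2"], 1)        # identical sequences
  expect_equal(loc["s1", "s3"], 0.75)     # local optimum aligns "ACG": 3/4
  expect_equal(unname(diag(loc)), rep(1, 3))
  # protein default scoring on near-identical sequences
  aa <- c(p = "MKVLAT", q = "MKVLAT", r = "MKVGAT")
  glo <- simValues(alignmentSimilarity(aa, mode = "global"))
  expect_equal(glo["p", "q"], 1)
  expect_true(glo["p", "r"] > 0.5 && glo["p", "r"] < 1)
  expect_true(all(glo >= 0 & glo <= 1))
})

test_that("alignment similarity errors name residues outside the alphabet
           and permuting input order permutes the matrix", {
  expect_error(alignmentSimilarity(c(a = "MKX1", b = "MKVL")),
               "alphabet.*1")
  aa <- c(p = "MKVLAT", q = "MKIGAT", r = "WQRNDE")
  s1 <- simValues(alignmentSimilarity(aa))
  s2 <- simValues(alignmentSimilarity(aa[c(3, 1, 2)]))
  expect_equal(s2[names(aa), names(aa)], s1)
})

test_that("measure correlations are computed on strict upper triangles", {
  v <- randomSimilarity(8, seed = 42)
  m1 <- similarityMatrix(v, "drug", "m1")
  w <- 1 - v; diag(w) <- 1
  m2 <- similarityMatrix(w, "drug", "m2")
  rho <- measureCorrelations(list(m1, m2))
  expect_equal(rho["m1", "m1"], 1)
  expect_equal(rho["m1", "m2"], -1)  # perfect negative linear map off-diag
  # independent random matrices decorrelate as n grows
  big1 <- similarityMatrix(randomSimilarity(40, seed = 1), "drug", "r1")
  big2 <- similarityMatrix(randomSimilarity(40, seed = 2), "drug", "r2")
  expect_lt(abs(measureCorrelations(list(big1, big2))["r1", "r2"]), 0.1)
  # constant matrix flagged as NA with a warning
  const <- similarityMatrix(matrix(1, 8, 8, dimnames = dimnames(v)),
                            "drug", "const")
  expect_warning(rho2 <- measureCorrelations(list(m1, const)), "constant")
  expect_true(is.na(rho2["m1", "const"]))
})
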