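# Brute-force wrapper evaluation over every valid combination; the greedy
# search must reach the same optimum on landscapes with one dominant pair.
exhaustiveBest <- function(catalog, Wdt0, folds, metric, integration) {
  enum <- enumerateValidCombinations(catalog)
  best <- -Inf
  for (od in enum$drugSubsets) {
    for (ot in enum$targetSubsets) {
      v <- estimatePRF(od, ot, catalog, Wdt0, folds, metric = metric,
                       integration = integration)
      if (v > best) best <- v
    }
  }
  best
}

referenceLayout <- list(
  drug = c(Structures = "Structures", DDA_Jac = "DDA", DDA_Cos = "DDA",
           DDI_Jac = "DDI", DDI_Cos = "DDI", SE_Jac = "SE", SE_Cos = "SE"),
  target = c(Seq_Loc = "Seq", Seq_Glo = "Seq", PPI_ISP = "PPI",
             PPI_Jac = "PPI", PPI_Cos = "PPI", GO_Wang = "GO",
             GO_Jiang = "GO", PW_Jac = "PW", PW_Cos = "PW"))

test_that("combination enumeration respects the same-dataset exclusion
           rule", {
  # 7 drug measures over 4 datasets, 9 target measures over 4 datasets:
  # (2*3*3*3 - 1) * (3*4*3*3 - 1) subsets
  enum <- enumerateValidCombinations(referenceLayout)
  expect_equal(length(enum$drugSubsets), 53)
  expect_equal(length(enum$targetSubsets), 107)
  expect_equal(enum$count, 5671)
  # no emitted subset carries a repeated dataset
  for (ss in enum$drugSubsets)
    expect_false(anyDuplicated(referenceLayout$drug[ss]) > 0)
  # one measure per side -> a single combination
  expect_equal(enumerateValidCombinations(
    list(drug = c(a = "A"), target = c(b = "B")))$count, 1)
  # two drug measures sharing a dataset can only appear alone
  expect_equal(enumerateValidCombinations(
    list(drug = c(a = "X", b = "X"), target = c(c = "C")))$count, 2)
  # without exclusion: all non-empty subsets
  expect_equal(enumerateValidCombinations(referenceLayout,
                                          exclusion = FALSE)$count,
               (2^7 - 1) * (2^9 - 1))
})

test_that("the wrapper criterion is deterministic for fixed folds and near
           chance on shuffled labels", {
  b <- generateBundle(selectionSpec(2))
  ct <- bundleProfileCatalog(b)
  folds <- makeFolds(b$dti, 5, seed = 4)
  v1 <- estimatePRF("DDA_Jac", "PW_Jac", ct, b$dti, folds, metric = "AUC")
  v2 <- estimatePRF("DDA_Jac", "PW_Jac", ct, b$dti, folds, metric = "AUC")
  expect_identical(v1, v2)
  expect_gt(v1, 0.8)  # informative pair carries strong signal
  # destroying the link structure drops AUC to chance
  set.seed(9)
  shuffled <- b$dti
  shuffled[] <- sample(shuffled)
  foldsS <- makeFolds(shuffled, 5, seed = 4)
  vNull <- estimatePRF("DDA_Jac", "PW_Jac", ct, shuffled, foldsS,
                       metric = "AUC")
  expect_lt(abs(vNull - 0.5), 0.07)
  expect_error(estimatePRF(character(), "PW_Jac", ct, b$dti, folds),
               "non-empty")
})

test_that("forward selection on a single-pair catalog returns that pair
           with a one-step trace", {
  b <- generateBundle(strongSignalSpec(5))
  ct <- bundleProfileCatalog(b)  # one drug + one target measure
  res <- forwardSimilarityIntegration(ct, b$dti, metric = "AUPR",
                                      nFolds = 5, seed = 3)
  expect_equal(res@OD, "DDA_Jac")
  expect_equal(res@OT, "PW_Jac")
  expect_equal(nrow(res@trace), 1)
  expect_equal(res@finalPRF, res@trace$PRF[1])
})

test_that("forward selection reaches the exhaustive optimum when one
           informative pair dominates noise measures", {
  b <- generateBundle(selectionSpec(7))
  ct <- bundleProfileCatalog(b)
  folds <- makeFolds(b$dti, 5, seed = 8)
  res <- forwardSimilarityIntegration(ct, b$dti, metric = "AUPR",
                                      integration = "AVG", folds = folds)
  expect_true("DDA_Jac" %in% res@OD)
  expect_true("PW_Jac" %in% res@OT)
  best <- exhaustiveBest(ct, b$dti, folds, "AUPR", "AVG")
  expect_equal(res@finalPRF, best, tolerance = 1e-12)
})

test_that("forward selection is deterministic and its trace strictly
           improves", {
  b <- generateBundle(selectionSpec(12))
  ct <- bundleProfileCatalog(b)
  folds <- makeFolds(b$dti, 5, seed = 2)
  r1 <- forwardSimilarityIntegration(ct, b$dti, folds = folds)
  r2 <- forwardSimilarityIntegration(ct, b$dti, folds = folds)
  expect_identical(r1@trace, r2@trace)
  expect_identical(r1@OD, r2@OD)
  if (nrow(r1@trace) > 1)
    expect_true(all(diff(r1@trace$PRF) > 0))
  # bounded model count: |AD||AT| at step 1 plus per-step candidate sets
  expect_lte(r1@evaluations, 3 * 3 + sum(3 + 3 + 9))
})

test_that("dataset exclusion constrains greedy candidates, not only the
           enumeration", {
  # two drug measures on one dataset: at most one may ever be selected
  b <- generateBundle(selectionSpec(15))
  ct0 <- bundleProfileCatalog(b)
  # re-tag the two noise drug measures as one shared dataset
  entries <- ct0@entries
  for (i in seq_along(entries)) {
    if (measureName(entries[[i]]) %in% c("DX1_Jac", "DX2_Jac"))
      entries[[i]] <- similarityMatrix(simValues(entries[[i]]), "drug",
                                       measureName(entries[[i]]),
                                       datasetTag = "DX")
  }
  ct <- similarityCatalog(entries)
  res <- forwardSimilarityIntegration(ct, b$dti, nFolds = 5, seed = 2)
  tags <- vapply(res@OD, function(nm) datasetTag(ct[[nm]]), character(1))
  expect_false(anyDuplicated(tags) > 0)
  enum <- enumerateValidCombinations(ct)
  for (ss in enum$drugSubsets) {
    t2 <- vapply(ss, function(nm) datasetTag(ct[[nm]]), character(1))
    expect_false(anyDuplicated(t2) > 0)
  }
})
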