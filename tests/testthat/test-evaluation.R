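test_that("fold assignment partitions positives and negatives separately
           into near-equal, reproducible parts", {
  W0 <- matrix(0, 5, 4, dimnames = list(paste0("d", 1:5), paste0("t", 1:4)))
  W0[c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19)] <- 1
  f <- makeFolds(W0, nFolds = 5, seed = 9)
  expect_equal(unname(table(f@posFold)), rep(2L, 5), ignore_attr = TRUE)
  sizes <- table(f@negFold)
  expect_lte(max(sizes) - min(sizes), 1)
  # determinism
  f2 <- makeFolds(W0, nFolds = 5, seed = 9)
  expect_identical(f@posFold, f2@posFold)
  expect_identical(f@negFold, f2@negFold)
  # disjoint cover of all pairs
  expect_setequal(c(f@posIdx, f@negIdx), seq_along(W0))
  expect_error(makeFolds(matrix(c(1, 0, 0, 0), 2), nFolds = 2),
               "fewer positive")
})

test_that("fold sizes on a network with 3,583 positives split 10 ways are
           358 or 359", {
  W0 <- matrix(0, 862, 1517)
  set.seed(4)
  W0[sample(length(W0), 3583)] <- 1
  rownames(W0) <- paste0("d", 1:862); colnames(W0) <- paste0("t", 1:1517)
  f <- makeFolds(W0, nFolds = 10, seed = 1)
  expect_setequal(unique(as.integer(table(f@posFold))), c(358L, 359L))
})

test_that("confusion metrics match hand-computed values", {
  got <- confusionMetrics(tp = 1, fp = 1, fn = 2, tn = 6)
  expect_equal(got[["PRE"]], 0.5)
  expect_equal(got[["REC"]], 1 / 3)
  expect_equal(got[["F1"]], 0.4)
  expect_equal(got[["ACC"]], 0.7)
  expect_equal(got[["MCC"]], 4 / sqrt(336))
  # zero denominators are defined as 0
  expect_equal(unname(confusionMetrics(0, 0, 3, 7)[c("PRE", "MCC")]),
               c(0, 0))
})

test_that("threshold-free metrics behave at the extremes and match an
           independent AUC implementation", {
  s <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  l <- c(1, 1, 1, 0, 0)
  perfect <- computeMetrics(s, l)
  expect_equal(perfect$AUC, 1)
  expect_equal(perfect$AUPR, 1)
  expect_equal(perfect$F1, 1)
  expect_equal(perfect$MCC, 1)
  reversed <- computeMetrics(s, 1 - l)
  expect_equal(reversed$AUC, 0)
  # rank-statistic AUC equals ROC-curve integration (pROC), ties included
  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    set.seed(seed)
    sc <- sample(seq(0, 1, by = 0.1), 60, replace = TRUE)
    lb <- rbinom(60, 1, 0.3)
    if (length(unique(lb)) < 2) next
    expect_equal(aucScore(sc, lb),
                 as.numeric(pROC::auc(pROC::roc(
                   lb, sc, quiet = TRUE, direction = "<",
                   levels = c(0, 1)))),
                 tolerance = 1e-12)
  }
})

test_that("stepwise AUPR equals exhaustive threshold enumeration", {
  # brute-force average precision: precision at every positive, averaged
  bruteAP <- function(scores, labels) {
    ord <- order(-scores)
    l <- labels[ord]
    sum((cumsum(l) / seq_along(l))[l == 1]) / sum(l)
  }
  for (seed in 1:5) {
    set.seed(seed)
    sc <- runif(40)  # distinct scores: both formulations coincide
    lb <- rbinom(40, 1, 0.3)
    if (length(unique(lb)) < 2) next
    expect_equal(auprScore(sc, lb), bruteAP(sc, lb), tolerance = 1e-12)
  }
})

test_that("single-class labels are flagged rather than scored", {
  expect_warning(out <- computeMetrics(c(0.2, 0.8), c(1, 1)),
                 "single-class")
  expect_true(is.na(out$AUC))
})

test_that("cross-validation on a no-signal network is at chance and test
           positives never leak into training", {
  b <- generateBundle(nullSignalSpec(3))
  net <- bundleNetwork(b, "DDA_Jac", "PW_Jac")
  folds <- makeFolds(b$dti, 10, seed = 5)
  rep <- crossValidate(net, folds)
  expect_equal(nrow(rep), 10)
  expect_lt(abs(mean(rep$AUC) - 0.5), 0.05)
  # leakage guard: zeroing test positives leaves only training links
  for (f in 1:3) {
    testPos <- folds@posIdx[folds@posFold == f]
    Wtrain <- b$dti
    Wtrain[testPos] <- 0
    expect_equal(sum(Wtrain[testPos]), 0)
    expect_equal(sum(Wtrain) + length(testPos), sum(b$dti))
  }
})

test_that("cross-validated AUPR on a strongly planted network rises an
           order of magnitude above prevalence", {
  b <- generateBundle(strongSignalSpec(11))
  net <- bundleNetwork(b, "DDA_Jac", "PW_Jac")
  folds <- makeFolds(b$dti, 10, seed = 2)
  rep <- crossValidate(net, folds)
  prevalence <- mean(b$dti)
  expect_gte(mean(rep$AUPR) / prevalence, 10)
})

test_that("the decay-factor sweep credits tied optima and accounts
           percentages correctly", {
  b <- generateBundle(strongSignalSpec(21))
  ct <- bundleProfileCatalog(b)
  models <- list(
    m1 = list(Wdd = normalizeSimilarity(simValues(ct[["DDA_Jac"]])),
              Wtt = normalizeSimilarity(simValues(ct[["PW_Jac"]]))))
  folds <- makeFolds(b$dti, 5, seed = 3)
  sweep <- decayFactorSweep(models, b$dti, folds,
                            alphas = c(0.1, 0.5, 0.9), metrics = "AUC")
  counts <- sweep$counts
  # one model: counts per metric sum to >= 1 (exactly 1 without ties)
  expect_gte(sum(counts$count), 1)
  expect_equal(sum(counts$percent) >= 100, TRUE)
  nTies <- nrow(sweep$best) - 1
  expect_equal(sum(counts$count), 1 + nTies)
  # determinism: re-running yields identical tables
  sweep2 <- decayFactorSweep(models, b$dti, folds,
                             alphas = c(0.1, 0.5, 0.9), metrics = "AUC")
  expect_identical(sweep$counts, sweep2$counts)
})

test_that("small decay factors dominate AUC optima on contraction-dominated
           synthetic models", {
  bestAlphas <- numeric()
  for (seed in 31:33) {
    b <- generateBundle(strongSignalSpec(seed))
    ct <- bundleProfileCatalog(b)
    models <- list(m = list(
      Wdd = normalizeSimilarity(simValues(ct[["DDA_Jac"]])),
      Wtt = normalizeSimilarity(simValues(ct[["PW_Jac"]]))))
    folds <- makeFolds(b$dti, 5, seed = 1)
    sweep <- decayFactorSweep(models, b$dti, folds,
                              alphas = c(0.1, 0.5, 0.9), metrics = "AUC")
    bestAlphas <- c(bestAlphas, sweep$best$alpha)
  }
  # direction only: the small decay factor is the most frequent optimum
  expect_gte(sum(bestAlphas == 0.1), sum(bestAlphas == 0.9))
  expect_gte(sum(bestAlphas == 0.1), sum(bestAlphas == 0.5))
})

test_that("edge permutation preserves the association count and destroys
           planted signal", {
  X <- randomProfiles(15, 25, seed = 8, density = 0.3)
  P <- permuteProfileEdges(X, seed = 4)
  expect_equal(sum(P), sum(X))
  expect_equal(dim(P), dim(X))
  expect_identical(P, permuteProfileEdges(X, seed = 4))
  expect_false(identical(P, permuteProfileEdges(X, seed = 5)))
  # all-zero matrix unchanged
  Z <- X * 0
  expect_equal(permuteProfileEdges(Z, seed = 1), Z)
})

test_that("paired t-test comparisons match a hand-computed textbook case
           and degenerate safely", {
  a <- data.frame(AUPR = c(0.50, 0.61, 0.70, 0.43, 0.68))
  b <- data.frame(AUPR = c(0.43, 0.55, 0.62, 0.41, 0.60))
  got <- compareModels(a, b, "AUPR", alternative = "greater")
  d <- a$AUPR - b$AUPR
  tHand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$t, tHand)
  expect_equal(got$p, pt(tHand, df = 4, lower.tail = FALSE))
  # identical reports: zero difference, not significant
  same <- compareModels(a, a, "AUPR")
  expect_equal(same$meanDiff, 0)
  expect_false(same$significant05)
  # constant shift with tiny noise is significant at 0.01
  set.seed(2)
  noise <- rnorm(10, sd = 1e-4)
  hi <- data.frame(AUC = 0.8 + noise)
  lo <- data.frame(AUC = 0.7 + noise / 2)
  expect_true(compareModels(hi, lo, "AUC")$significant01)
  expect_error(compareModels(a, data.frame(AUPR = 1:3), "AUPR"),
               "equal fold counts")
})

test_that("random-integration baselines sample valid combinations
           reproducibly and an informative model beats them", {
  b <- generateBundle(selectionSpec(41))
  ct <- bundleProfileCatalog(b)
  folds <- makeFolds(b$dti, 5, seed = 6)
  base <- randomIntegrationBaseline(ct, b$dti, folds, nModels = 12,
                                    seed = 13)
  expect_equal(length(base$reports), 12)
  base2 <- randomIntegrationBaseline(ct, b$dti, folds, nModels = 12,
                                     seed = 13)
  expect_identical(base$selections, base2$selections)
  expect_error(randomIntegrationBaseline(ct, b$dti, folds, nModels = 1e6),
               "exceeds")
  inform <- metricMeans(crossValidate(
    bundleNetwork(b, "DDA_Jac", "PW_Jac"), folds))["AUPR"]
  beaten <- vapply(base$reports,
                   function(r) inform >= mean(r$AUPR), logical(1))
  expect_gte(mean(beaten), 0.9)
})
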