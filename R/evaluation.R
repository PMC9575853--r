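#' @include AllClasses.R utils.R propagation.R
NULL

#' Stratified cross-validation folds over drug-target pairs
#'
#' Known (positive) pairs and unknown pairs (treated as negatives under the
#' closed-world assumption) are each randomly divided into \code{nFolds}
#' near-equal parts; each part serves as test data in turn while the
#' remaining positives form the training interaction matrix.
#'
#' @param Wdt0 binary interaction matrix, or a [HeterogeneousNetwork].
#' @param nFolds number of folds (>= 2; default 10).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return a [FoldAssignment].
#' @export
makeFolds <- function(Wdt0, nFolds = 10L, seed = 1L) {
  if (is(Wdt0, "HeterogeneousNetwork")) Wdt0 <- Wdt0@Wdt0
  Wdt0 <- as.matrix(Wdt0)
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L) stop("'nFolds' must be >= 2")
  posIdx <- which(Wdt0 == 1)
  negIdx <- which(Wdt0 == 0)
  if (length(posIdx) < nFolds)
    stop("fewer positive pairs (", length(posIdx), ") than folds")
  lab <- withLocalSeed(seed, list(
    pos = sample(rep_len(seq_len(nFolds), length(posIdx))),
    neg = sample(rep_len(seq_len(nFolds), length(negIdx)))))
  new("FoldAssignment", nFolds = nFolds,
      posIdx = as.integer(posIdx), posFold = as.integer(lab$pos),
      negIdx = as.integer(negIdx), negFold = as.integer(lab$neg),
      dims = dim(Wdt0), seed = as.integer(seed))
}

#' Confusion-matrix metrics
#'
#' Precision, recall, F1, accuracy and the Matthews correlation coefficient
#' from the four confusion counts. Any metric with a zero denominator is
#' defined as 0.
#'
#' @param tp,fp,fn,tn confusion counts.
#' @return named numeric vector (PRE, REC, F1, ACC, MCC).
#' @examples
#' confusionMetrics(1, 1, 2, 6)  # MCC = 4 / sqrt(336)
#' @export
confusionMetrics <- function(tp, fp, fn, tn) {
  div <- function(num, den) if (den > 0) num / den else 0
  pre <- div(tp, tp + fp)
  rec <- div(tp, tp + fn)
  f1 <- div(2 * pre * rec, pre + rec)
  acc <- div(tp + tn, tp + fp + fn + tn)
  mccDen <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mccDen > 0) (tp * tn - fp * fn) / mccDen else 0
  c(PRE = pre, REC = rec, F1 = f1, ACC = acc, MCC = mcc)
}

#' Area under the ROC curve via the rank statistic
#'
#' Equivalent to the Wilcoxon/Mann-Whitney statistic; ties receive average
#' ranks, matching trapezoidal integration of the ROC curve.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive).
#' @return AUC in \[0, 1\]; \code{NA} if only one class is present.
#' @export
aucScore <- function(scores, labels) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) integration: precision is evaluated at each
#' distinct score threshold and weighted by the recall increment, i.e. the
#' average-precision formulation suited to heavily imbalanced link
#' prediction.
#'
#' @inheritParams aucScore
#' @return AUPR in \[0, 1\]; \code{NA} if only one class is present.
#' @export
auprScore <- function(scores, labels) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- c(s[-1L] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Threshold-free and thresholded metrics for one score vector
#'
#' Computes AUC and AUPR plus the confusion metrics at a binary decision
#' threshold. The default threshold rule picks the score cut maximising F1
#' on the evaluated pairs (the choice is reported); alternatively a fixed
#' numeric threshold can be supplied.
#'
#' @inheritParams aucScore
#' @param thresholdRule "maxF1" (default) or "fixed".
#' @param threshold numeric cut used when \code{thresholdRule = "fixed"};
#'   scores >= threshold are predicted positive.
#' @return one-row data.frame: AUPR, AUC, PRE, REC, F1, ACC, MCC, threshold.
#' @export
computeMetrics <- function(scores, labels, thresholdRule = c("maxF1", "fixed"),
                           threshold = NULL) {
  thresholdRule <- match.arg(thresholdRule)
  if (length(scores) != length(labels))
    stop("scores and labels must align")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    warning("single-class labels: AUC/AUPR undefined")
  auc <- aucScore(scores, labels)
  aupr <- auprScore(scores, labels)
  if (thresholdRule == "fixed") {
    if (is.null(threshold)) stop("fixed rule needs a 'threshold'")
    thr <- threshold
  } else {
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; l <- labels[ord]
    tp <- cumsum(l); fp <- cumsum(1 - l)
    last <- c(s[-1L] != s[-length(s)], TRUE)
    f1 <- 2 * tp[last] / (2 * tp[last] + fp[last] + (npos - tp[last]))
    thr <- s[last][which.max(f1)]
  }
  pred <- as.integer(scores >= thr)
  cm <- confusionMetrics(tp = sum(pred == 1 & labels == 1),
                         fp = sum(pred == 1 & labels == 0),
                         fn = sum(pred == 0 & labels == 1),
                         tn = sum(pred == 0 & labels == 0))
  data.frame(AUPR = aupr, AUC = auc, PRE = cm["PRE"], REC = cm["REC"],
             F1 = cm["F1"], ACC = cm["ACC"], MCC = cm["MCC"],
             threshold = thr, row.names = NULL)
}

#' Cross-validated evaluation of a heterogeneous network model
#'
#' For each fold the test-fold positives are removed (zeroed) from the
#' training interaction matrix, scores are propagated, and metrics are
#' computed on the test-fold pairs only (its positives plus its share of
#' the unknown pairs). The similarity layers of \code{net} must already be
#' normalised; they do not depend on the interaction matrix, so they are
#' shared across folds.
#'
#' @param net a [HeterogeneousNetwork] with normalised Wdd/Wtt.
#' @param folds a [FoldAssignment] built on \code{net}'s interaction matrix.
#' @param alpha,tol,maxIter propagation settings, see [propagateNetwork()].
#' @param thresholdRule,threshold see [computeMetrics()].
#' @return data.frame with one row per fold (fold, AUPR, AUC, PRE, REC, F1,
#'   ACC, MCC, threshold); an error is raised naming the fold if
#'   propagation fails to converge.
#' @export
crossValidate <- function(net, folds, alpha = 0.1, tol = 1e-6,
                          maxIter = 1000L, thresholdRule = "maxF1",
                          threshold = NULL) {
  stopifnot(is(net, "HeterogeneousNetwork"), is(folds, "FoldAssignment"))
  if (!all(dim(net@Wdt0) == folds@dims))
    stop("fold assignment does not match the interaction matrix")
  W0 <- net@Wdt0
  rows <- vector("list", folds@nFolds)
  for (f in seq_len(folds@nFolds)) {
    testPos <- folds@posIdx[folds@posFold == f]
    testNeg <- folds@negIdx[folds@negFold == f]
    Wtrain <- W0
    Wtrain[testPos] <- 0
    trained <- propagateNetwork(
      new("HeterogeneousNetwork", Wdd = net@Wdd, Wtt = net@Wtt,
          Wdt0 = Wtrain),
      alpha = alpha, tol = tol, maxIter = maxIter)
    if (!trained@converged)
      stop("propagation did not converge in fold ", f)
    testIdx <- c(testPos, testNeg)
    labels <- c(rep(1L, length(testPos)), rep(0L, length(testNeg)))
    row <- computeMetrics(trained@scores[testIdx], labels,
                          thresholdRule = thresholdRule,
                          threshold = threshold)
    rows[[f]] <- cbind(fold = f, row)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean of each metric across folds
#' @param report per-fold data.frame from [crossValidate()].
#' @return named numeric vector of fold means.
#' @export
metricMeans <- function(report) {
  cols <- intersect(c("AUPR", "AUC", "PRE", "REC", "F1", "ACC", "MCC"),
                    names(report))
  colMeans(report[, cols, drop = FALSE])
}

#' Decay-factor sweep
#'
#' Runs cross-validation for every model at every decay factor and records,
#' per model and metric, which decay factor attains the maximum. Ties
#' credit every tied value, so percentages can exceed 100 only when ties
#' occur.
#'
#' @param models named list; each element is a list with normalised
#'   \code{Wdd} and \code{Wtt} matrices.
#' @param Wdt0 shared binary interaction matrix.
#' @param folds shared [FoldAssignment].
#' @param alphas decay factors to scan (default 0.1 to 1 by 0.1).
#' @param metrics metrics to tally (default AUC, AUPR, F1).
#' @param ... further arguments to [crossValidate()].
#' @return list with \code{best} (one row per model x metric x tied alpha)
#'   and \code{counts} (per alpha x metric: count and percent of models).
#' @export
decayFactorSweep <- function(models, Wdt0, folds,
                             alphas = seq(0.1, 1, by = 0.1),
                             metrics = c("AUC", "AUPR", "F1"), ...) {
  stopifnot(length(models) > 0, !is.null(names(models)))
  perf <- list()
  for (mn in names(models)) {
    net0 <- new("HeterogeneousNetwork", Wdd = models[[mn]]$Wdd,
                Wtt = models[[mn]]$Wtt, Wdt0 = as.matrix(Wdt0))
    perf[[mn]] <- vapply(alphas, function(a) {
      metricMeans(crossValidate(net0, folds, alpha = a, ...))[metrics]
    }, numeric(length(metrics)))
    if (is.null(dim(perf[[mn]])))
      perf[[mn]] <- matrix(perf[[mn]], nrow = 1,
                           dimnames = list(metrics, NULL))
  }
  best <- do.call(rbind, lapply(names(models), function(mn) {
    do.call(rbind, lapply(metrics, function(met) {
      v <- perf[[mn]][met, ]
      tied <- alphas[v >= max(v) - 1e-12]
      data.frame(model = mn, metric = met, alpha = tied)
    }))
  }))
  counts <- do.call(rbind, lapply(metrics, function(met) {
    b <- best[best$metric == met, ]
    data.frame(metric = met, alpha = alphas,
               count = vapply(alphas, function(a)
                 sum(abs(b$alpha - a) < 1e-12), numeric(1)))
  }))
  counts$percent <- 100 * counts$count / length(models)
  list(best = best, counts = counts)
}

#' Permute the edges of a binary profile matrix
#'
#' Null-model ablation: the existing 1-entries are reassigned to uniformly
#' random (entity, feature) cells without collision, preserving the total
#' number of associations while destroying their structure. Deterministic
#' given the seed.
#'
#' @param profiles binary entity x feature matrix.
#' @param seed integer seed.
#' @return permuted matrix with identical dimensions, dimnames and number
#'   of 1s.
#' @export
permuteProfileEdges <- function(profiles, seed = 1L) {
  X <- .checkProfiles(profiles)
  k <- sum(X)
  out <- X * 0
  if (k > 0) {
    cells <- withLocalSeed(seed, sample(length(X), k))
    out[cells] <- 1
  }
  out
}

#' Random-integration baseline models
#'
#' Samples valid (drug subset, target subset) combinations uniformly
#' without replacement from the constrained enumeration (see
#' [enumerateValidCombinations()]), integrates and evaluates each on the
#' shared folds. Serves as the null distribution against which the
#' forward-selected model is compared.
#'
#' @param catalog a [SimilarityCatalog].
#' @param Wdt0 binary interaction matrix.
#' @param folds shared [FoldAssignment].
#' @param nModels number of random models (must not exceed the number of
#'   valid combinations; equal to it reproduces exhaustive evaluation).
#' @param method integration function, see [pairwiseCombine()].
#' @param seed integer seed for the sample.
#' @param ... further arguments to [crossValidate()].
#' @return list with \code{selections} (data.frame of sampled subsets) and
#'   \code{reports} (list of per-fold metric data.frames).
#' @export
randomIntegrationBaseline <- function(catalog, Wdt0, folds, nModels = 100L,
                                      method = "AVG", seed = 1L, ...) {
  enum <- enumerateValidCombinations(catalog)
  if (nModels > enum$count)
    stop("nModels (", nModels, ") exceeds the ", enum$count,
         " valid combinations")
  picks <- withLocalSeed(seed, sample(enum$count, nModels))
  nT <- length(enum$targetSubsets)
  reports <- vector("list", nModels)
  sel <- vector("list", nModels)
  for (i in seq_len(nModels)) {
    di <- (picks[i] - 1L) %/% nT + 1L
    ti <- (picks[i] - 1L) %% nT + 1L
    od <- enum$drugSubsets[[di]]
    ot <- enum$targetSubsets[[ti]]
    Wdd <- normalizeSimilarity(integrateSimilaritySet(
      lapply(od, function(nm) catalog[[nm]]), method = method))
    Wtt <- normalizeSimilarity(integrateSimilaritySet(
      lapply(ot, function(nm) catalog[[nm]]), method = method))
    net <- new("HeterogeneousNetwork", Wdd = Wdd, Wtt = Wtt,
               Wdt0 = as.matrix(Wdt0))
    reports[[i]] <- crossValidate(net, folds, ...)
    sel[[i]] <- data.frame(model = i,
                           drugs = paste(od, collapse = "+"),
                           targets = paste(ot, collapse = "+"))
  }
  list(selections = do.call(rbind, sel), reports = reports)
}

#' Compare two cross-validated models with a t-test
#'
#' Paired across folds by default (the fold assignment is shared between
#' candidate models, so per-fold differences are the natural unit);
#' one-sided "greater" by default for testing improvement claims. If the
#' per-fold differences have zero variance the test degenerates: the
#' p-value is 1 when the mean difference does not favour the alternative
#' and 0 when it strictly does.
#'
#' @param reportA,reportB per-fold data.frames from [crossValidate()].
#' @param metric metric column to compare (default "AUPR").
#' @param alternative "greater" (default), "less" or "two.sided"; the
#'   alternative is that A's mean exceeds B's.
#' @param paired logical; unpaired uses Welch's t-test.
#' @return data.frame: metric, meanDiff, t, p, significant05, significant01.
#' @export
compareModels <- function(reportA, reportB, metric = "AUPR",
                          alternative = c("greater", "less", "two.sided"),
                          paired = TRUE) {
  alternative <- match.arg(alternative)
  a <- reportA[[metric]]; b <- reportB[[metric]]
  if (is.null(a) || is.null(b)) stop("metric '", metric, "' not found")
  if (paired && length(a) != length(b))
    stop("paired comparison needs equal fold counts")
  meanDiff <- mean(a) - mean(b)
  degenerate <- if (paired) stats::sd(a - b) == 0 else
    (stats::sd(a) == 0 && stats::sd(b) == 0)
  if (degenerate) {
    p <- switch(alternative,
      greater = if (meanDiff > 0) 0 else 1,
      less = if (meanDiff < 0) 0 else 1,
      two.sided = if (meanDiff != 0) 0 else 1)
    tstat <- if (meanDiff == 0) 0 else sign(meanDiff) * Inf
  } else {
    tt <- stats::t.test(a, b, paired = paired, alternative = alternative)
    p <- unname(tt$p.value)
    tstat <- unname(tt$statistic)
  }
  data.frame(metric = metric, meanDiff = meanDiff, t = tstat, p = p,
             significant05 = p < 0.05, significant01 = p < 0.01)
}
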