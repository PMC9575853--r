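#' @include AllClasses.R utils.R integration.R evaluation.R
NULL

#' Enumerate valid measure subsets for one side
#'
#' All non-empty subsets of the given measures that contain at most one
#' measure per dataset tag (the same-dataset exclusion rule: measures
#' computed from one data source are strongly correlated and are never
#' integrated together). With exclusion off, all non-empty subsets are
#' returned. Subsets are emitted in a deterministic order derived from the
#' declaration order.
#'
#' @param tags named character vector: names are measure names, values are
#'   dataset tags, in canonical (declaration) order.
#' @param exclusion apply the same-dataset rule (default TRUE).
#' @return list of character vectors (measure subsets).
#' @export
enumerateMeasureSubsets <- function(tags, exclusion = TRUE) {
  stopifnot(!is.null(names(tags)))
  if (exclusion) {
    groups <- split(names(tags), factor(tags, levels = unique(tags)))
    # per group: none (NA) or one member; cartesian product minus all-none
    choices <- lapply(groups, function(g) c(NA_character_, g))
    grid <- expand.grid(rev(choices), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[, rev(seq_along(choices)), drop = FALSE]
    subsets <- apply(grid, 1L, function(row) row[!is.na(row)],
                     simplify = FALSE)
  } else {
    n <- length(tags)
    subsets <- lapply(seq_len(2^n) - 1L, function(mask) {
      names(tags)[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    })
  }
  subsets[lengths(subsets) > 0L]
}

#' Enumerate valid (drug subset, target subset) combinations
#'
#' Every pair of a non-empty drug-measure subset and a non-empty
#' target-measure subset such that no two selected measures on one side
#' share a dataset tag. For the reference layout of 7 drug measures
#' (Structures x1, DDA x2, DDI x2, SE x2) and 9 target measures (Seq x2,
#' PPI x3, GO x2, PW x2) this yields 53 x 107 = 5,671 combinations.
#'
#' @param catalog a [SimilarityCatalog], or a list with named character
#'   vectors \code{drug} and \code{target} mapping measure names to dataset
#'   tags (so combination counts can be computed without materialising
#'   matrices).
#' @param exclusion apply the same-dataset rule (default TRUE).
#' @return list with \code{count}, \code{drugSubsets} and
#'   \code{targetSubsets}; combination \code{i} (1-based, row-major over
#'   drug subsets) pairs \code{drugSubsets[[(i - 1) \%/\% nT + 1]]} with
#'   \code{targetSubsets[[(i - 1) \%\% nT + 1]]}.
#' @export
enumerateValidCombinations <- function(catalog, exclusion = TRUE) {
  if (is(catalog, "SimilarityCatalog")) {
    sides <- vapply(catalog@entries, measureSide, character(1))
    tg <- vapply(catalog@entries, datasetTag, character(1))
    nm <- vapply(catalog@entries, measureName, character(1))
    drugTags <- stats::setNames(tg[sides == "drug"], nm[sides == "drug"])
    targetTags <- stats::setNames(tg[sides == "target"], nm[sides == "target"])
  } else {
    drugTags <- catalog$drug
    targetTags <- catalog$target
  }
  if (length(drugTags) < 1L || length(targetTags) < 1L)
    stop("catalog needs at least one drug and one target measure")
  ds <- enumerateMeasureSubsets(drugTags, exclusion)
  ts <- enumerateMeasureSubsets(targetTags, exclusion)
  list(count = length(ds) * length(ts), drugSubsets = ds, targetSubsets = ts)
}

#' Cross-validated performance of one similarity selection
#'
#' Integrates the ordered drug and target measure lists (Algorithm 2's
#' sequential pairwise fold), normalises both layers, runs cross-validation
#' on the fixed fold assignment and returns the mean of the configured
#' metric across folds. Reusing one fold assignment for every candidate
#' model keeps the wrapper comparisons paired.
#'
#' @param OD,OT ordered character vectors of drug / target measure names.
#' @param catalog a [SimilarityCatalog].
#' @param Wdt0 binary interaction matrix.
#' @param folds a [FoldAssignment].
#' @param metric "AUPR" (default), "AUC" or "F1".
#' @param integration integration function, see [pairwiseCombine()].
#' @param snfK,snfT SNF hyperparameters.
#' @param ... further arguments to [crossValidate()].
#' @return scalar mean performance.
#' @export
estimatePRF <- function(OD, OT, catalog, Wdt0, folds, metric = "AUPR",
                        integration = "AVG", snfK = NULL, snfT = 20, ...) {
  if (length(OD) < 1L || length(OT) < 1L)
    stop("OD and OT must be non-empty")
  Wdd <- normalizeSimilarity(integrateSimilaritySet(
    lapply(OD, function(nm) catalog[[nm]]), method = integration,
    snfK = snfK, snfT = snfT))
  Wtt <- normalizeSimilarity(integrateSimilaritySet(
    lapply(OT, function(nm) catalog[[nm]]), method = integration,
    snfK = snfK, snfT = snfT))
  net <- new("HeterogeneousNetwork", Wdd = Wdd, Wtt = Wtt,
             Wdt0 = as.matrix(Wdt0))
  report <- crossValidate(net, folds, ...)
  mean(report[[match.arg(metric, c("AUPR", "AUC", "F1"))]])
}

#' Forward similarity integration (FSI)
#'
#' Greedy forward selection of the drug and target similarity measures to
#' integrate. The first step evaluates every valid single-measure (drug,
#' target) pair and keeps the best. Each later step considers three moves:
#' adding the best (drug, target) pair jointly, adding only a drug measure,
#' or adding only a target measure; the best of the three is accepted only
#' if it strictly improves the cross-validated criterion. The search stops
#' at the first non-improving step or when either remaining pool is
#' exhausted. Candidates whose dataset tag is already represented on their
#' side are skipped when exclusion is on; argmax ties are broken by
#' canonical catalog order, and ties between the three move types prefer
#' drug-only, then target-only, then joint. Deterministic given the
#' catalog, fold seed and configuration.
#'
#' @param catalog a [SimilarityCatalog] of candidate measures.
#' @param Wdt0 binary known-interaction matrix (drugs x targets).
#' @param metric wrapper criterion: "AUPR" (default), "AUC" or "F1".
#' @param integration "AVG" (default), "MIN", "MAX" or "SNF".
#' @param folds optional [FoldAssignment]; built from \code{nFolds} and
#'   \code{seed} when absent and reused for every candidate.
#' @param nFolds,seed fold construction when \code{folds} is missing.
#' @param exclusion enforce the same-dataset rule (default TRUE).
#' @param snfK,snfT SNF hyperparameters.
#' @param ... further arguments to [crossValidate()] (alpha, tol, ...).
#' @return an [FSIResult]; its trace has strictly increasing performance.
#' @export
forwardSimilarityIntegration <- function(catalog, Wdt0, metric = "AUPR",
                                         integration = "AVG", folds = NULL,
                                         nFolds = 10L, seed = 1L,
                                         exclusion = TRUE, snfK = NULL,
                                         snfT = 20, ...) {
  stopifnot(is(catalog, "SimilarityCatalog"))
  metric <- match.arg(metric, c("AUPR", "AUC", "F1"))
  if (is.null(folds)) folds <- makeFolds(Wdt0, nFolds = nFolds, seed = seed)
  AD <- measureNames(catalog, "drug")
  AT <- measureNames(catalog, "target")
  if (length(AD) < 1L || length(AT) < 1L)
    stop("catalog needs measures on both sides")
  tagOf <- function(nm) datasetTag(catalog[[nm]])
  nEval <- 0L
  prf <- function(od, ot) {
    nEval <<- nEval + 1L
    estimatePRF(od, ot, catalog, Wdt0, folds, metric = metric,
                integration = integration, snfK = snfK, snfT = snfT, ...)
  }
  validCands <- function(pool, selected) {
    if (!exclusion) return(pool)
    used <- vapply(selected, tagOf, character(1))
    pool[!vapply(pool, tagOf, character(1)) %in% used]
  }
  OD <- character(); OT <- character()
  RD <- AD; RT <- AT
  prfPrev <- 0
  k <- 0L
  traceRows <- list()
  repeat {
    k <- k + 1L
    candD <- validCands(RD, OD)
    candT <- validCands(RT, OT)
    # joint addition (Algorithm 1 line 4)
    bothBest <- -Inf; bothX <- NULL; bothY <- NULL
    nCand <- 0L
    for (x in candD) for (y in candT) {
      nCand <- nCand + 1L
      v <- prf(c(OD, x), c(OT, y))
      if (v > bothBest) { bothBest <- v; bothX <- x; bothY <- y }
    }
    if (k == 1L) {
      if (nCand == 0L) stop("no valid candidate pair at the first step")
      prfK <- bothBest
      X <- bothX; Y <- bothY
    } else {
      drugBest <- -Inf; drugX <- NULL
      for (x in candD) {
        nCand <- nCand + 1L
        v <- prf(c(OD, x), OT)
        if (v > drugBest) { drugBest <- v; drugX <- x }
      }
      targetBest <- -Inf; targetY <- NULL
      for (y in candT) {
        nCand <- nCand + 1L
        v <- prf(OD, c(OT, y))
        if (v > targetBest) { targetBest <- v; targetY <- y }
      }
      prfK <- max(bothBest, drugBest, targetBest)
      if (!is.finite(prfK)) break
      if (prfK == drugBest) { X <- drugX; Y <- NULL }
      else if (prfK == targetBest) { X <- NULL; Y <- targetY }
      else { X <- bothX; Y <- bothY }
    }
    if (!(prfK > prfPrev)) break
    OD <- c(OD, X); OT <- c(OT, Y)
    RD <- setdiff(RD, X); RT <- setdiff(RT, Y)
    traceRows[[k]] <- data.frame(
      step = k, candidates = nCand,
      addedDrug = if (is.null(X)) NA_character_ else X,
      addedTarget = if (is.null(Y)) NA_character_ else Y,
      PRF = prfK)
    prfPrev <- prfK
    if (length(RD) == 0L || length(RT) == 0L) break
  }
  trace <- if (length(traceRows)) do.call(rbind, traceRows) else
    data.frame(step = integer(), candidates = integer(),
               addedDrug = character(), addedTarget = character(),
               PRF = numeric())
  new("FSIResult", OD = OD, OT = OT, trace = trace, finalPRF = prfPrev,
      metric = metric, integration = toupper(integration),
      evaluations = nEval)
}
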