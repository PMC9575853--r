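#' @import methods
NULL

#' SimilarityMatrix: labelled pairwise similarities for one entity side
#'
#' A square, symmetric matrix of pairwise similarity scores in \[0, 1\] for a
#' set of drugs or a set of targets, tagged with the measure that produced it
#' and the underlying data source. The dataset tag backs the same-dataset
#' exclusion rule used during similarity-subset search: two measures derived
#' from one source (e.g. Jaccard and cosine on the same association table)
#' are strongly correlated and are never integrated together.
#'
#' @slot values numeric matrix, square, symmetric, entries in \[0, 1\],
#'   unit diagonal; dimnames carry the entity identifiers.
#' @slot side character, \code{"drug"} or \code{"target"}.
#' @slot measureName character, e.g. \code{"DDA_Jac"}.
#' @slot datasetTag character, the source dataset, e.g. \code{"DDA"}.
#'
#' @seealso [similarityMatrix()] for the validated constructor,
#'   [tanimotoSimilarity()] and friends for the kernels that produce these.
#' @export
setClass("SimilarityMatrix",
  representation(
    values      = "matrix",
    side        = "character",
    measureName = "character",
    datasetTag  = "character"
  )
)

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
  if (nrow(v) != ncol(v)) msg <- c(msg, "'values' must be square")
  ids <- rownames(v)
  if (is.null(ids) || is.null(colnames(v)) || !identical(ids, colnames(v)))
    msg <- c(msg, "row and column names must be identical entity ids")
  if (!is.null(ids) && anyDuplicated(ids))
    msg <- c(msg, "entity ids must be unique")
  if (length(object@side) != 1L || !object@side %in% c("drug", "target"))
    msg <- c(msg, "'side' must be \"drug\" or \"target\"")
  if (is.numeric(v) && nrow(v) > 0L) {
    if (max(abs(v - t(v))) > 1e-8)
      msg <- c(msg, "matrix must be symmetric (tolerance 1e-8)")
    if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
      msg <- c(msg, "values must lie in [0, 1]")
    if (max(abs(diag(v) - 1)) > 1e-9)
      msg <- c(msg, "diagonal must equal 1")
  }
  if (length(msg)) msg else TRUE
})

#' SimilarityCatalog: a named collection of similarity measures
#'
#' Holds the candidate drug-drug and target-target [SimilarityMatrix]
#' objects offered to the forward-selection search. Declaration order is the
#' canonical order used for deterministic tie-breaking. All drug-side members
#' must share one drug universe and all target-side members one target
#' universe.
#'
#' @slot entries list of [SimilarityMatrix], uniquely named by measure.
#' @export
setClass("SimilarityCatalog", representation(entries = "list"))

setValidity("SimilarityCatalog", function(object) {
  e <- object@entries
  msg <- character()
  if (!all(vapply(e, is, logical(1), class2 = "SimilarityMatrix")))
    return("all entries must be SimilarityMatrix objects")
  nm <- vapply(e, function(x) x@measureName, character(1))
  if (anyDuplicated(nm)) msg <- c(msg, "measure names must be unique")
  for (s in c("drug", "target")) {
    idx <- which(vapply(e, function(x) x@side, character(1)) == s)
    if (length(idx) > 1L) {
      ref <- rownames(e[[idx[1L]]]@values)
      same <- vapply(idx[-1L], function(i)
        identical(rownames(e[[i]]@values), ref), logical(1))
      if (!all(same))
        msg <- c(msg, sprintf("all %s-side matrices must share entity ids", s))
    }
  }
  if (length(msg)) msg else TRUE
})

#' HeterogeneousNetwork: drug layer, target layer, bipartite DTI layer
#'
#' The three-layer graph over which interaction scores are propagated: a
#' drug-drug similarity matrix \eqn{W_{dd}}, a target-target similarity
#' matrix \eqn{W_{tt}}, and the binary known drug-target interaction matrix
#' \eqn{W_{dt}^0} linking the two sides.
#'
#' @slot Wdd numeric drug-drug matrix (m x m), dimnames = drug ids.
#' @slot Wtt numeric target-target matrix (n x n), dimnames = target ids.
#' @slot Wdt0 binary m x n matrix of known interactions.
#' @export
setClass("HeterogeneousNetwork",
  representation(Wdd = "matrix", Wtt = "matrix", Wdt0 = "matrix")
)

setValidity("HeterogeneousNetwork", function(object) {
  msg <- character()
  m <- nrow(object@Wdt0); n <- ncol(object@Wdt0)
  if (nrow(object@Wdd) != m || ncol(object@Wdd) != m)
    msg <- c(msg, "Wdd dimension must match the number of drugs in Wdt0")
  if (nrow(object@Wtt) != n || ncol(object@Wtt) != n)
    msg <- c(msg, "Wtt dimension must match the number of targets in Wdt0")
  if (!all(object@Wdt0 %in% c(0, 1)))
    msg <- c(msg, "Wdt0 entries must be 0 or 1")
  if (!is.null(rownames(object@Wdt0)) && !is.null(rownames(object@Wdd)) &&
      !identical(rownames(object@Wdt0), rownames(object@Wdd)))
    msg <- c(msg, "drug ids of Wdd and Wdt0 must agree")
  if (!is.null(colnames(object@Wdt0)) && !is.null(rownames(object@Wtt)) &&
      !identical(colnames(object@Wdt0), rownames(object@Wtt)))
    msg <- c(msg, "target ids of Wtt and Wdt0 must agree")
  if (length(msg)) msg else TRUE
})

#' PropagationResult: converged drug-target scores
#'
#' @slot scores m x n numeric matrix of propagated interaction scores.
#' @slot iterations integer, iterations executed.
#' @slot converged logical, whether the max-absolute-change norm fell below
#'   the tolerance before the iteration cap.
#' @slot alpha numeric, decay factor used.
#' @slot tol numeric, convergence tolerance used.
#' @export
setClass("PropagationResult",
  representation(scores = "matrix", iterations = "integer",
                 converged = "logical", alpha = "numeric", tol = "numeric")
)

#' FoldAssignment: stratified cross-validation folds over DTI pairs
#'
#' Positive (known) and negative (unknown, closed world) drug-target pairs
#' are partitioned separately into near-equal folds, so every fold preserves
#' the prevalence of the full network.
#'
#' @slot nFolds integer fold count.
#' @slot posIdx integer linear indices (column-major, into the m x n
#'   interaction matrix) of positive pairs.
#' @slot posFold integer fold label per positive pair.
#' @slot negIdx integer linear indices of negative pairs.
#' @slot negFold integer fold label per negative pair.
#' @slot dims integer c(m, n) of the interaction matrix.
#' @slot seed integer seed the assignment was drawn with.
#' @export
setClass("FoldAssignment",
  representation(nFolds = "integer", posIdx = "integer", posFold = "integer",
                 negIdx = "integer", negFold = "integer", dims = "integer",
                 seed = "integer")
)

#' FSIResult: outcome of the forward similarity integration search
#'
#' @slot OD character, ordered selected drug measures (integration order).
#' @slot OT character, ordered selected target measures.
#' @slot trace data.frame with one row per accepted step: step, candidate
#'   counts considered, the chosen additions, and the accepted performance.
#' @slot finalPRF numeric, cross-validated performance of the final model.
#' @slot metric character, wrapper criterion ("AUC", "AUPR" or "F1").
#' @slot integration character, integration function used ("AVG", "MIN",
#'   "MAX" or "SNF").
#' @slot evaluations integer, number of candidate models evaluated.
#' @export
setClass("FSIResult",
  representation(OD = "character", OT = "character", trace = "data.frame",
                 finalPRF = "numeric", metric = "character",
                 integration = "character", evaluations = "integer")
)
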