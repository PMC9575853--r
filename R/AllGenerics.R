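#' @include AllClasses.R
NULL

#' Entity identifiers of a similarity object
#' @param x a [SimilarityMatrix] or [HeterogeneousNetwork].
#' @param ... unused.
#' @return character vector of ids (for a network, use [drugIds()] /
#'   [targetIds()]).
#' @export
setGeneric("entityIds", function(x, ...) standardGeneric("entityIds"))

#' Numeric similarity values
#' @param x a [SimilarityMatrix].
#' @return the underlying numeric matrix with id dimnames.
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))

#' Side (drug or target) of a similarity measure
#' @param x a [SimilarityMatrix].
#' @export
setGeneric("measureSide", function(x) standardGeneric("measureSide"))

#' Measure name
#' @param x a [SimilarityMatrix].
#' @export
setGeneric("measureName", function(x) standardGeneric("measureName"))

#' Source dataset tag of a similarity measure
#' @param x a [SimilarityMatrix].
#' @export
setGeneric("datasetTag", function(x) standardGeneric("datasetTag"))

#' Measure names held by a catalog
#' @param x a [SimilarityCatalog].
#' @param side optional filter, "drug" or "target".
#' @export
setGeneric("measureNames", function(x, side = NULL) standardGeneric("measureNames"))

#' Drug identifiers
#' @param x a [HeterogeneousNetwork] or [PropagationResult].
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' Target identifiers
#' @param x a [HeterogeneousNetwork] or [PropagationResult].
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))

#' Propagated interaction scores
#' @param x a [PropagationResult].
#' @export
setGeneric("interactionScores", function(x) standardGeneric("interactionScores"))

setMethod("entityIds", "SimilarityMatrix", function(x, ...) rownames(x@values))
setMethod("simValues", "SimilarityMatrix", function(x) x@values)
setMethod("measureSide", "SimilarityMatrix", function(x) x@side)
setMethod("measureName", "SimilarityMatrix", function(x) x@measureName)
setMethod("datasetTag", "SimilarityMatrix", function(x) x@datasetTag)

setMethod("measureNames", "SimilarityCatalog", function(x, side = NULL) {
  nm <- vapply(x@entries, measureName, character(1))
  if (!is.null(side)) {
    nm <- nm[vapply(x@entries, measureSide, character(1)) == side]
  }
  unname(nm)
})

setMethod("drugIds", "HeterogeneousNetwork", function(x) rownames(x@Wdt0))
setMethod("targetIds", "HeterogeneousNetwork", function(x) colnames(x@Wdt0))
setMethod("drugIds", "PropagationResult", function(x) rownames(x@scores))
setMethod("targetIds", "PropagationResult", function(x) colnames(x@scores))
setMethod("interactionScores", "PropagationResult", function(x) x@scores)

#' @describeIn SimilarityCatalog-class number of measures.
#' @param x a SimilarityCatalog.
#' @export
setMethod("length", "SimilarityCatalog", function(x) length(x@entries))

#' @describeIn SimilarityCatalog-class extract one measure by name or position.
#' @param i index or measure name.
#' @param j,... unused.
#' @export
setMethod("[[", "SimilarityCatalog", function(x, i, j, ...) {
  if (is.character(i)) {
    hit <- match(i, vapply(x@entries, measureName, character(1)))
    if (is.na(hit)) stop("no measure named '", i, "' in catalog")
    i <- hit
  }
  x@entries[[i]]
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix '%s' [%s/%s]: %d x %d entities\n",
              object@measureName, object@side, object@datasetTag,
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "SimilarityCatalog", function(object) {
  sides <- vapply(object@entries, measureSide, character(1))
  cat(sprintf("SimilarityCatalog: %d measures (%d drug, %d target)\n",
              length(object@entries), sum(sides == "drug"),
              sum(sides == "target")))
  for (e in object@entries)
    cat(sprintf("  %-14s %-6s %s\n", measureName(e), measureSide(e),
                datasetTag(e)))
})

setMethod("show", "HeterogeneousNetwork", function(object) {
  m <- nrow(object@Wdt0); n <- ncol(object@Wdt0)
  pos <- sum(object@Wdt0)
  cat(sprintf(
    "HeterogeneousNetwork: %d drugs, %d targets, %d known DTIs (%.4f%%)\n",
    m, n, pos, if (m * n > 0) 100 * pos / (m * n) else 0))
})

setMethod("show", "PropagationResult", function(object) {
  cat(sprintf(
    "PropagationResult: %d x %d scores, alpha = %g, %d iterations (%s)\n",
    nrow(object@scores), ncol(object@scores), object@alpha,
    object@iterations,
    if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "FSIResult", function(object) {
  cat(sprintf("FSIResult (%s integration, %s criterion)\n",
              object@integration, object@metric))
  cat("  OD:", paste(object@OD, collapse = ", "), "\n")
  cat("  OT:", paste(object@OT, collapse = ", "), "\n")
  cat(sprintf("  final %s = %.4f after %d accepted steps (%d models evaluated)\n",
              object@metric, object@finalPRF, nrow(object@trace),
              object@evaluations))
})
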