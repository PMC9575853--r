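#' @include AllClasses.R
NULL

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All package randomness is routed through
# this so that no function disturbs global RNG state.
withLocalSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Force exact symmetry and a unit diagonal; used by every kernel so stored
# matrices satisfy the SimilarityMatrix invariants bit-for-bit.
.finishSimilarity <- function(v, ids) {
  v <- (v + t(v)) / 2
  v[v < 0] <- 0
  v[v > 1] <- 1
  diag(v) <- 1
  dimnames(v) <- list(ids, ids)
  v
}

#' Construct a validated SimilarityMatrix
#'
#' @param values square numeric matrix; dimnames taken as entity ids (or
#'   supplied via \code{ids}).
#' @param side "drug" or "target".
#' @param measureName name of the measure (defaults to "custom").
#' @param datasetTag source dataset tag (defaults to the measure name).
#' @param ids optional character vector of entity ids.
#' @return a [SimilarityMatrix].
#' @examples
#' m <- matrix(c(1, .3, .3, 1), 2, 2)
#' similarityMatrix(m, "drug", "toy", ids = c("d1", "d2"))
#' @export
similarityMatrix <- function(values, side, measureName = "custom",
                             datasetTag = measureName, ids = NULL) {
  values <- as.matrix(values)
  if (!is.null(ids)) dimnames(values) <- list(ids, ids)
  if (is.null(rownames(values)))
    stop("entity ids required (matrix dimnames or 'ids')")
  new("SimilarityMatrix", values = values, side = side,
      measureName = measureName, datasetTag = datasetTag)
}

#' Assemble a SimilarityCatalog
#'
#' @param ... [SimilarityMatrix] objects, or a single list of them.
#'   Declaration order is the canonical tie-break order for selection.
#' @return a [SimilarityCatalog].
#' @export
similarityCatalog <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1L]]) &&
      !is(entries[[1L]], "SimilarityMatrix"))
    entries <- entries[[1L]]
  new("SimilarityCatalog", entries = entries)
}

#' Assemble a heterogeneous drug-target network
#'
#' Aligns the drug and target similarity layers to the interaction matrix by
#' id and returns the validated three-layer network.
#'
#' @param Wdd drug-drug [SimilarityMatrix] or plain matrix.
#' @param Wtt target-target [SimilarityMatrix] or plain matrix.
#' @param Wdt0 binary m x n matrix of known interactions with drug ids as
#'   rownames and target ids as colnames.
#' @return a [HeterogeneousNetwork].
#' @export
heterogeneousNetwork <- function(Wdd, Wtt, Wdt0) {
  if (is(Wdd, "SimilarityMatrix")) Wdd <- simValues(Wdd)
  if (is(Wtt, "SimilarityMatrix")) Wtt <- simValues(Wtt)
  Wdt0 <- as.matrix(Wdt0)
  if (!is.null(rownames(Wdt0)) && !is.null(rownames(Wdd))) {
    if (!setequal(rownames(Wdt0), rownames(Wdd)))
      stop("drug ids of Wdd and Wdt0 differ")
    Wdd <- Wdd[rownames(Wdt0), rownames(Wdt0), drop = FALSE]
  }
  if (!is.null(colnames(Wdt0)) && !is.null(rownames(Wtt))) {
    if (!setequal(colnames(Wdt0), rownames(Wtt)))
      stop("target ids of Wtt and Wdt0 differ")
    Wtt <- Wtt[colnames(Wdt0), colnames(Wdt0), drop = FALSE]
  }
  new("HeterogeneousNetwork", Wdd = Wdd, Wtt = Wtt, Wdt0 = Wdt0)
}

# Binary incidence matrix checks shared by the profile kernels.
.checkProfiles <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) == 0L) stop("profile set contains no entities")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("e", seq_len(nrow(profiles)))
  if (anyDuplicated(rownames(profiles))) stop("entity ids must be unique")
  if (!all(profiles %in% c(0, 1)))
    stop("profiles must be binary (0/1)")
  storage.mode(profiles) <- "double"
  profiles
}
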