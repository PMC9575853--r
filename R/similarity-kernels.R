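#' @include AllClasses.R utils.R
NULL

#' ConfidenceGraph: undirected interaction graph with edge confidences
#'
#' Represents a protein-protein interaction (PPI) network in which each edge
#' carries a confidence score in \[0, 1\] indicating how likely the
#' interaction is to be real. Similarity kernels filter the graph at a
#' confidence threshold before use.
#'
#' @slot nodes character vector of node ids.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{confidence}; undirected, each pair stored once, no self-loops.
#' @export
setClass("ConfidenceGraph",
  representation(nodes = "character", edges = "data.frame"))

setValidity("ConfidenceGraph", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("from", "to", "confidence") %in% names(e)))
    return("edges need columns from, to, confidence")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "node ids must be unique")
  unknown <- setdiff(c(e$from, e$to), object@nodes)
  if (length(unknown))
    msg <- c(msg, paste0("edge references unknown node(s): ",
                         paste(head(unknown, 5), collapse = ", ")))
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$confidence < 0 | e$confidence > 1))
      msg <- c(msg, "confidences must lie in [0, 1]")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) msg <- c(msg, "each undirected pair stored once")
  }
  if (length(msg)) msg else TRUE
})

#' Build a ConfidenceGraph
#'
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{confidence} (numeric in \[0, 1\]).
#' @param nodes optional node universe; defaults to the nodes seen in
#'   \code{edges}. Nodes without edges are kept as isolated vertices.
#' @return a [ConfidenceGraph].
#' @export
confidenceGraph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) >= 3 && !all(c("from", "to", "confidence") %in% names(edges)))
    names(edges)[1:3] <- c("from", "to", "confidence")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  new("ConfidenceGraph", nodes = as.character(nodes), edges = edges)
}

setMethod("show", "ConfidenceGraph", function(object) {
  cat(sprintf("ConfidenceGraph: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
})

# Pairwise similarity of the rows of a binary incidence matrix. `dot` based
# formulation: on binary vectors Tanimoto and Jaccard coincide. Pairs where
# either vector is all-zero are defined as 0 (off-diagonal) to avoid 0/0.
.binaryRowSimilarity <- function(X, index = c("jaccard", "cosine")) {
  index <- match.arg(index)
  dot <- tcrossprod(X)
  size <- rowSums(X)
  denom <- switch(index,
    jaccard = outer(size, size, "+") - dot,
    cosine  = sqrt(outer(size, size)))
  v <- ifelse(denom > 0, dot / denom, 0)
  .finishSimilarity(v, rownames(X))
}

#' Tanimoto similarity between binary profiles
#'
#' For binary profile vectors \eqn{r_i, r_j} (rows of the incidence matrix)
#' the Tanimoto score is
#' \eqn{r_i \cdot r_j / (\|r_i\|^2 + \|r_j\|^2 - r_i \cdot r_j)}, the
#' standard fingerprint similarity for chemical structures. On binary
#' vectors it coincides with the Jaccard index.
#'
#' @param profiles binary entity x feature matrix (rownames = entity ids),
#'   entry 1 marking an existing association.
#' @param side entity side, "drug" (default) or "target".
#' @param measureName,datasetTag labels stored on the result.
#' @return a [SimilarityMatrix]; pairs involving an all-zero profile score 0,
#'   the diagonal is 1.
#' @examples
#' p <- rbind(d1 = c(1, 1, 0), d2 = c(1, 0, 1))
#' simValues(tanimotoSimilarity(p))["d1", "d2"]  # 1/3
#' @export
tanimotoSimilarity <- function(profiles, side = "drug",
                               measureName = "Tanimoto",
                               datasetTag = "Structures") {
  X <- .checkProfiles(profiles)
  similarityMatrix(.binaryRowSimilarity(X, "jaccard"), side,
                   measureName, datasetTag)
}

#' Jaccard similarity between binary profiles
#'
#' \eqn{u \cdot v / (\|u\|^2 + \|v\|^2 - u \cdot v)} on binary association
#' vectors; identical in functional form to [tanimotoSimilarity()].
#'
#' @inheritParams tanimotoSimilarity
#' @return a [SimilarityMatrix].
#' @export
jaccardSimilarity <- function(profiles, side = "drug",
                              measureName = "Jaccard",
                              datasetTag = measureName) {
  X <- .checkProfiles(profiles)
  similarityMatrix(.binaryRowSimilarity(X, "jaccard"), side,
                   measureName, datasetTag)
}

#' Cosine similarity between binary profiles
#'
#' \eqn{u \cdot v / (\|u\| \|v\|)} on binary association vectors.
#'
#' @inheritParams tanimotoSimilarity
#' @return a [SimilarityMatrix].
#' @export
cosineSimilarity <- function(profiles, side = "drug",
                             measureName = "Cosine",
                             datasetTag = measureName) {
  X <- .checkProfiles(profiles)
  similarityMatrix(.binaryRowSimilarity(X, "cosine"), side,
                   measureName, datasetTag)
}

#' Inverse shortest-path transform
#'
#' The raw distance-to-similarity transform \eqn{S = A e^{-bD}} applied to a
#' shortest-path hop distance \eqn{D}. At \eqn{D = 0} it returns \eqn{A};
#' unreachable pairs (\eqn{D = \infty}) map to 0.
#'
#' @param D numeric hop distance(s), may be \code{Inf}.
#' @param A amplitude, 0 < A <= 1 (default 0.9).
#' @param b decay rate per hop, b > 0 (default 1).
#' @return numeric similarity value(s).
#' @examples
#' ispTransform(0)            # 0.9
#' ispTransform(1)            # 0.9 * exp(-1)
#' @export
ispTransform <- function(D, A = 0.9, b = 1) {
  if (A <= 0 || A > 1) stop("'A' must lie in (0, 1]")
  if (b <= 0) stop("'b' must be positive")
  out <- A * exp(-b * D)
  out[is.infinite(D)] <- 0
  out
}

# Confidence-filtered igraph over the full node set (isolates kept).
.filteredIgraph <- function(graph, minConfidence) {
  stopifnot(is(graph, "ConfidenceGraph"))
  if (minConfidence < 0 || minConfidence > 1)
    stop("'minConfidence' must lie in [0, 1]")
  e <- graph@edges[graph@edges$confidence >= minConfidence, , drop = FALSE]
  igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                vertices = data.frame(name = graph@nodes))
}

#' Inverse shortest-path (ISP) similarity on a confidence-filtered graph
#'
#' Edges below the confidence threshold are dropped, hop distances
#' \eqn{D(p, p')} of shortest paths are computed on the filtered graph
#' (unit edge weights, breadth-first), and distances are transformed with
#' [ispTransform()]. Unreachable pairs score 0; the stored diagonal is 1
#' (maximal self-similarity) even though the raw transform gives \eqn{A} at
#' \eqn{D = 0} -- the raw transform remains available as [ispTransform()].
#'
#' @param graph a [ConfidenceGraph].
#' @param A,b transform parameters, see [ispTransform()].
#' @param minConfidence edge filter threshold (default 0.5).
#' @param side entity side of the result (default "target").
#' @param measureName,datasetTag labels stored on the result.
#' @return a [SimilarityMatrix].
#' @export
ispSimilarity <- function(graph, A = 0.9, b = 1, minConfidence = 0.5,
                          side = "target", measureName = "PPI_ISP",
                          datasetTag = "PPI") {
  g <- .filteredIgraph(graph, minConfidence)
  D <- igraph::distances(g, weights = NA)
  v <- ispTransform(D, A = A, b = b)
  similarityMatrix(.finishSimilarity(v, graph@nodes), side,
                   measureName, datasetTag)
}

#' Common-neighbour similarity on a confidence-filtered graph
#'
#' Each node is represented by its binary adjacency vector on the filtered
#' graph; the Jaccard or cosine index is then applied to those vectors
#' (the PPI_Jac / PPI_Cos measures).
#'
#' @inheritParams ispSimilarity
#' @param index "jaccard" or "cosine".
#' @return a [SimilarityMatrix].
#' @export
commonNeighborSimilarity <- function(graph, index = c("jaccard", "cosine"),
                                     minConfidence = 0.5, side = "target",
                                     measureName = NULL, datasetTag = "PPI") {
  index <- match.arg(index)
  g <- .filteredIgraph(graph, minConfidence)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  adj <- (adj > 0) * 1
  rownames(adj) <- graph@nodes
  if (is.null(measureName))
    measureName <- if (index == "jaccard") "PPI_Jac" else "PPI_Cos"
  similarityMatrix(.binaryRowSimilarity(adj, index), side,
                   measureName, datasetTag)
}

#' Normalised pairwise alignment similarity between sequences
#'
#' Computes raw pairwise alignment scores \eqn{s(a, b)} with the
#' Smith-Waterman (local) or Needleman-Wunsch (global) algorithm and
#' normalises them to \eqn{s(a, b) / \sqrt{s(a, a)\, s(b, b)}}. Global
#' scores may be negative, so normalised values are clamped into \[0, 1\].
#'
#' @param sequences named character vector of residue strings, or an
#'   \code{XStringSet} (names = entity ids).
#' @param mode "local" (Smith-Waterman, default) or "global"
#'   (Needleman-Wunsch).
#' @param substitutionMatrix a scoring matrix, or the name of one shipped
#'   with Biostrings (default "BLOSUM62" for proteins).
#' @param gapOpening,gapExtension gap penalties (positive costs; defaults
#'   10 and 0.5).
#' @param side entity side of the result (default "target").
#' @param measureName,datasetTag labels stored on the result.
#' @return a [SimilarityMatrix] with unit diagonal.
#' @export
alignmentSimilarity <- function(sequences, mode = c("local", "global"),
                                substitutionMatrix = "BLOSUM62",
                                gapOpening = 10, gapExtension = 0.5,
                                side = "target", measureName = NULL,
                                datasetTag = "Seq") {
  mode <- match.arg(mode)
  if (is.null(measureName))
    measureName <- if (mode == "local") "Seq_Loc" else "Seq_Glo"
  if (is.character(substitutionMatrix) && length(substitutionMatrix) == 1L) {
    matName <- substitutionMatrix
    e <- new.env()
    utils::data(list = matName, package = "Biostrings", envir = e)
    substitutionMatrix <- get(matName, envir = e)
  }
  seqs <- as.character(sequences)
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named by entity id")
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  if (any(nchar(seqs) == 0L)) stop("sequences must be non-empty")
  alphabet <- rownames(substitutionMatrix)
  residues <- unique(unlist(strsplit(seqs, "")))
  bad <- setdiff(residues, alphabet)
  if (length(bad))
    stop("residue(s) outside the substitution-matrix alphabet: ",
         paste(bad, collapse = ", "))
  n <- length(seqs)
  type <- if (mode == "local") "local" else "global"
  score <- function(p, s) {
    Biostrings::pairwiseAlignment(
      pattern = p, subject = s, type = type,
      substitutionMatrix = substitutionMatrix,
      gapOpening = gapOpening, gapExtension = gapExtension,
      scoreOnly = TRUE)
  }
  self <- vapply(seqs, function(s) score(s, s), numeric(1), USE.NAMES = FALSE)
  if (any(self <= 0))
    stop("non-positive self-alignment score; normalisation undefined")
  v <- diag(1, n)
  for (i in seq_len(max(0, n - 1L))) {
    js <- (i + 1L):n
    raw <- score(Biostrings::BStringSet(seqs[js]), seqs[i])
    v[i, js] <- raw / sqrt(self[i] * self[js])
  }
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  similarityMatrix(.finishSimilarity(v, ids), side, measureName, datasetTag)
}

#' Pearson correlations between similarity measures
#'
#' Each similarity matrix is vectorised over its strict upper triangle
#' (diagonal excluded) and Pearson correlation coefficients are computed
#' between all pairs of measures on one entity side. Used as a redundancy
#' diagnostic: measures from one dataset correlate strongly, motivating the
#' same-dataset exclusion rule.
#'
#' @param measures a [SimilarityCatalog] or list of [SimilarityMatrix]
#'   objects sharing one side and one entity universe.
#' @return square numeric matrix of correlations named by measure; a
#'   constant-valued measure yields \code{NA} entries with a warning.
#' @export
measureCorrelations <- function(measures) {
  if (is(measures, "SimilarityCatalog")) measures <- measures@entries
  if (length(measures) < 1L) stop("no measures supplied")
  ids <- entityIds(measures[[1L]])
  ok <- vapply(measures, function(m) identical(entityIds(m), ids), logical(1))
  if (!all(ok)) stop("all measures must share entity ids")
  nm <- vapply(measures, measureName, character(1))
  ut <- upper.tri(simValues(measures[[1L]]))
  vecs <- vapply(measures, function(m) simValues(m)[ut],
                 numeric(sum(ut)))
  colnames(vecs) <- nm
  const <- apply(vecs, 2, function(x) stats::sd(x) == 0 || is.na(stats::sd(x)))
  if (any(const))
    warning("constant-valued measure(s), correlations undefined (NA): ",
            paste(nm[const], collapse = ", "))
  rho <- suppressWarnings(stats::cor(vecs))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho)[!const] <- 1
  rho
}
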