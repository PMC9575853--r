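#' @include AllClasses.R utils.R
NULL

#' Symmetric degree normalisation of a similarity matrix
#'
#' Rescales each entry by the geometric mean of its row and column sums,
#' \eqn{w(i,j) \gets w(i,j) / \sqrt{\sum_k w(i,k) \sum_k w(k,j)}}. With
#' this normalisation the propagation iteration over the heterogeneous
#' network is a contraction for decay factors below one and converges. The
#' self-similarity diagonal is included in the sums; rows with zero sum are
#' left at zero (isolated entities neither emit nor receive propagation).
#'
#' @param W a [SimilarityMatrix] or symmetric non-negative matrix.
#' @return a plain numeric matrix (symmetric; diagonal generally below 1, so
#'   this is not a [SimilarityMatrix]).
#' @examples
#' normalizeSimilarity(matrix(c(1, .5, .5, 1), 2))  # off-diagonal 1/3
#' @export
normalizeSimilarity <- function(W) {
  if (is(W, "SimilarityMatrix")) W <- simValues(W)
  W <- as.matrix(W)
  if (any(W < 0)) stop("similarity entries must be non-negative")
  if (nrow(W) != ncol(W)) stop("matrix must be square")
  if (max(abs(W - t(W))) > 1e-8) stop("matrix must be symmetric")
  rs <- rowSums(W)
  d <- ifelse(rs > 0, 1 / sqrt(rs), 0)
  out <- W * outer(d, d)
  (out + t(out)) / 2
}

#' Propagate interaction weights over the heterogeneous network
#'
#' Iterates \eqn{W^{i+1} = \alpha\, W_{dd} W^i W_{tt} + (1 - \alpha) W^0}
#' from the known-interaction matrix \eqn{W^0} until the maximum absolute
#' change falls below \code{tol} or \code{maxIter} is reached. \code{Wdd}
#' and \code{Wtt} must already be normalised (see [normalizeSimilarity()]);
#' with normalised layers and \eqn{\alpha < 1} the map is a contraction and
#' the fixed point is unique. The decay factor \eqn{\alpha} balances
#' network-propagated signal against the original interactions; the default
#' 0.1 keeps predictions anchored to the known network.
#'
#' @param net a [HeterogeneousNetwork] whose Wdd/Wtt are normalised, or
#'   normalised matrices passed via \code{Wdd}, \code{Wtt}, \code{Wdt0}.
#' @param alpha decay factor in \[0, 1\] (0 allowed as a degenerate value
#'   reproducing \eqn{W^0}).
#' @param tol convergence threshold on the max-absolute-change norm.
#' @param maxIter iteration cap.
#' @return a [PropagationResult]; non-convergence at \code{maxIter} is
#'   flagged, not an error.
#' @export
propagateNetwork <- function(net, alpha = 0.1, tol = 1e-6, maxIter = 1000L) {
  stopifnot(is(net, "HeterogeneousNetwork"))
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  if (tol <= 0) stop("'tol' must be positive")
  if (maxIter < 1) stop("'maxIter' must be >= 1")
  Wdd <- net@Wdd; Wtt <- net@Wtt; W0 <- net@Wdt0
  W <- W0
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    Wnext <- alpha * (Wdd %*% W %*% Wtt) + (1 - alpha) * W0
    delta <- max(abs(Wnext - W))
    W <- Wnext
    if (delta < tol) { converged <- TRUE; break }
  }
  dimnames(W) <- dimnames(W0)
  new("PropagationResult", scores = W, iterations = iter,
      converged = converged, alpha = alpha, tol = tol)
}

#' Rank candidate (novel) drug-target interactions
#'
#' Drops pairs already known and returns the remaining pairs sorted by
#' propagated score, ties broken lexicographically by (drug id, target id)
#' for determinism. Per-drug or per-target top-k views support case-study
#' style inspection of a single entity's best candidates.
#'
#' @param result a [PropagationResult] (or plain score matrix with ids as
#'   dimnames).
#' @param known binary known-interaction matrix aligned with the scores.
#' @param topK optional overall cap on returned rows.
#' @param perDrug,perTarget optional per-entity caps applied before the
#'   overall cap.
#' @return data.frame with columns \code{drug}, \code{target}, \code{score},
#'   best candidates first.
#' @export
rankNovelInteractions <- function(result, known, topK = NULL,
                                  perDrug = NULL, perTarget = NULL) {
  scores <- if (is(result, "PropagationResult")) result@scores else as.matrix(result)
  known <- as.matrix(known)
  if (!all(dim(scores) == dim(known)))
    stop("score and known matrices must share dimensions")
  keep <- which(known == 0)
  if (length(keep) == 0L)
    return(data.frame(drug = character(), target = character(),
                      score = numeric()))
  idx <- arrayInd(keep, dim(scores))
  out <- data.frame(
    drug = rownames(scores)[idx[, 1L]],
    target = colnames(scores)[idx[, 2L]],
    score = scores[keep],
    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$drug, out$target), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(perDrug))
    out <- do.call(rbind, lapply(split(out, out$drug), utils::head, perDrug))
  if (!is.null(perTarget))
    out <- do.call(rbind, lapply(split(out, out$target), utils::head, perTarget))
  if (!is.null(perDrug) || !is.null(perTarget)) {
    out <- out[order(-out$score, out$drug, out$target), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(topK)) out <- utils::head(out, topK)
  out
}
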