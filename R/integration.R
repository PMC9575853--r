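#' @include AllClasses.R utils.R
NULL

.rowNormalize <- function(W) {
  rs <- rowSums(W)
  rs[rs == 0] <- 1
  W / rs
}

# kNN "dominate set": keep the K largest entries of each row, zero the rest,
# then renormalise the surviving rows to sum to one. Ties at the K-th value
# are broken by column order.
.dominateSet <- function(W, K) {
  n <- nrow(W)
  K <- min(K, n)
  out <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    keep <- order(W[i, ], decreasing = TRUE)[seq_len(K)]
    out[i, keep] <- W[i, keep]
  }
  .rowNormalize(out)
}

#' Similarity network fusion of multiple similarity matrices
#'
#' Nonlinear fusion by iterative cross-diffusion. Each view is
#' row-normalised into a full transition kernel and restricted to a
#' row-normalised k-nearest-neighbour kernel; each iteration diffuses the
#' average of the other views through the kNN kernel
#' (\eqn{P^{(m)} \gets S^{(m)} \bar P^{(\neq m)} S^{(m)\top}}), restores the
#' diagonal (adds the identity) and symmetrises. After \code{t} iterations
#' the views are averaged, row-normalised, and symmetrised with a unit
#' half-diagonal: \eqn{(W + W^\top + I)/2}. This follows the semantics of
#' the published SNF reference implementations (SNFtool / SNFpy).
#'
#' @param mats list of square numeric matrices (same dimension/ids),
#'   non-negative similarities.
#' @param K neighbourhood size of the kNN kernel; default
#'   \code{min(20, n - 1)}.
#' @param t number of diffusion iterations (default 20).
#' @return the fused square matrix (not yet rescaled into \[0, 1\]).
#' @seealso [pairwiseCombine()] which wraps the fusion of two views and
#'   rescales the result into a valid [SimilarityMatrix].
#' @export
snfFuse <- function(mats, K = NULL, t = 20) {
  if (length(mats) < 2L) stop("SNF needs at least two views")
  n <- nrow(mats[[1L]])
  if (is.null(K)) K <- min(20L, n - 1L)
  if (K < 1L || t < 1L) stop("'K' and 't' must be >= 1")
  M <- length(mats)
  dn <- dimnames(mats[[1L]])
  aff <- lapply(mats, function(W) {
    W <- .rowNormalize(as.matrix(W))
    (W + t(W)) / 2
  })
  Wk <- lapply(aff, .dominateSet, K = K)
  Wsum <- Reduce("+", aff)
  for (iter in seq_len(t)) {
    for (m in seq_len(M)) {
      others <- (Wsum - aff[[m]]) / (M - 1)
      P <- Wk[[m]] %*% others %*% t(Wk[[m]])
      P <- P + diag(n)
      aff[[m]] <- (P + t(P)) / 2
    }
    Wsum <- Reduce("+", aff)
  }
  W <- Wsum / M
  W <- .rowNormalize(W)
  W <- (W + t(W) + diag(n)) / 2
  dimnames(W) <- dn
  W
}

.checkAligned <- function(A, B) {
  ia <- entityIds(A); ib <- entityIds(B)
  if (!identical(ia, ib)) {
    bad <- union(setdiff(ia, ib), setdiff(ib, ia))
    stop("similarity matrices are not aligned on entity ids",
         if (length(bad)) paste0("; mismatched: ",
                                 paste(head(bad, 5), collapse = ", "))
         else "; same ids in different order")
  }
  if (!identical(measureSide(A), measureSide(B)))
    stop("cannot combine measures from different sides")
}

#' Combine two similarity matrices
#'
#' Elementwise mean (\code{AVG}), minimum (\code{MIN}) or maximum
#' (\code{MAX}), or two-view similarity network fusion (\code{SNF}, see
#' [snfFuse()]). The fused SNF output is rescaled by its maximum
#' off-diagonal value so the result lives on the \[0, 1\] similarity scale
#' expected by the downstream propagation normalisation; the diagonal is
#' then reset to 1.
#'
#' @param A,B [SimilarityMatrix] objects aligned on entity ids and side.
#' @param method "AVG", "MIN", "MAX" or "SNF" (case-insensitive).
#' @param snfK,snfT SNF hyperparameters (neighbourhood size and iteration
#'   count), see [snfFuse()].
#' @return a [SimilarityMatrix] labelled as a combination.
#' @examples
#' a <- similarityMatrix(matrix(c(1, .2, .2, 1), 2), "drug", "a",
#'                       ids = c("x", "y"))
#' b <- similarityMatrix(matrix(c(1, .6, .6, 1), 2), "drug", "b",
#'                       ids = c("x", "y"))
#' simValues(pairwiseCombine(a, b, "AVG"))["x", "y"]  # 0.4
#' @export
pairwiseCombine <- function(A, B, method = c("AVG", "MIN", "MAX", "SNF"),
                            snfK = NULL, snfT = 20) {
  method <- toupper(method[1L])
  method <- match.arg(method, c("AVG", "MIN", "MAX", "SNF"))
  .checkAligned(A, B)
  a <- simValues(A); b <- simValues(B)
  v <- switch(method,
    AVG = (a + b) / 2,
    MIN = pmin(a, b),
    MAX = pmax(a, b),
    SNF = {
      f <- snfFuse(list(a, b), K = snfK, t = snfT)
      off <- f; diag(off) <- 0
      mx <- max(off)
      if (mx > 0) f <- f / mx
      f
    })
  similarityMatrix(.finishSimilarity(v, entityIds(A)), measureSide(A),
                   measureName = paste0(method, "(", measureName(A), ",",
                                        measureName(B), ")"),
                   datasetTag = "integrated")
}

#' Sequentially integrate an ordered set of similarity measures
#'
#' Folds the ordered measures pairwise left-to-right: the first two are
#' combined, then each further measure is combined with the running result.
#' For MIN/MAX the fold is order-invariant; for AVG it implies geometric
#' down-weighting of early measures (three matrices yield
#' \eqn{A/4 + B/4 + C/2}), and SNF is likewise order-dependent. The
#' integration order is the order of the supplied list -- under forward
#' selection, the selection order.
#'
#' @param measures ordered list of [SimilarityMatrix] objects on one side,
#'   or a [SimilarityCatalog] (its declaration order is used).
#' @param method,snfK,snfT see [pairwiseCombine()].
#' @return a [SimilarityMatrix]; a singleton list is returned unchanged.
#' @export
integrateSimilaritySet <- function(measures, method = "AVG",
                                   snfK = NULL, snfT = 20) {
  if (is(measures, "SimilarityCatalog")) measures <- measures@entries
  if (is(measures, "SimilarityMatrix")) measures <- list(measures)
  if (length(measures) == 0L) stop("empty similarity set")
  out <- measures[[1L]]
  for (i in seq_along(measures)[-1L])
    out <- pairwiseCombine(out, measures[[i]], method = method,
                           snfK = snfK, snfT = snfT)
  out
}
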