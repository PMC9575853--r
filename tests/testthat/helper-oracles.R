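# Independent oracles, written as literal transcriptions with explicit
# loops so they share no code path with the package implementations.

# Similarity network fusion exactly as in the published reference
# implementation (row-normalise + symmetrise each view, row-normalised
# K-nearest-neighbour kernel, cross-diffusion with identity restoration and
# symmetrisation each step, final average / row-normalise / (W + W' + I)/2).
snfOracle <- function(mats, K, t) {
  LW <- length(mats)
  n <- nrow(mats[[1L]])
  normalizeRows <- function(X) {
    out <- X
    for (i in seq_len(n)) {
      s <- sum(X[i, ])
      if (s > 0) out[i, ] <- X[i, ] / s
    }
    out
  }
  Wall <- vector("list", LW)
  for (j in seq_len(LW)) {
    W <- normalizeRows(mats[[j]])
    Wall[[j]] <- (W + t(W)) / 2
  }
  dominate <- function(W, K) {
    out <- matrix(0, n, n)
    for (i in seq_len(n)) {
      keep <- order(W[i, ], decreasing = TRUE)[seq_len(K)]
      out[i, keep] <- W[i, keep]
    }
    normalizeRows(out)
  }
  newW <- vector("list", LW)
  for (j in seq_len(LW)) newW[[j]] <- dominate(Wall[[j]], K)
  for (iter in seq_len(t)) {
    nextW <- vector("list", LW)
    for (j in seq_len(LW)) {
      sumWJ <- matrix(0, n, n)
      for (k in seq_len(LW)) if (k != j) sumWJ <- sumWJ + Wall[[k]]
      nextW[[j]] <- newW[[j]] %*% (sumWJ / (LW - 1)) %*% t(newW[[j]])
    }
    for (j in seq_len(LW)) {
      W <- nextW[[j]] + diag(n)
      Wall[[j]] <- (W + t(W)) / 2
    }
  }
  W <- matrix(0, n, n)
  for (j in seq_len(LW)) W <- W + Wall[[j]]
  W <- normalizeRows(W / LW)
  (W + t(W) + diag(n)) / 2
}

# Fixed point of the propagation by direct linear solve:
# vec(W) = (I - a * kron(Wtt', Wdd))^{-1} (1 - a) vec(W0).
propagationOracle <- function(Wdd, Wtt, W0, alpha) {
  mn <- length(W0)
  A <- diag(mn) - alpha * kronecker(t(Wtt), Wdd)
  matrix(solve(A, (1 - alpha) * as.vector(W0)), nrow(W0), ncol(W0))
}

# Random symmetric similarity matrix with unit diagonal.
randomSimilarity <- function(n, seed, ids = sprintf("e%02d", seq_len(n))) {
  set.seed(seed)
  v <- matrix(runif(n * n), n)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  dimnames(v) <- list(ids, ids)
  v
}

# Random binary profile matrix.
randomProfiles <- function(n, p, seed, density = 0.4,
                           ids = sprintf("e%02d", seq_len(n))) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, density), n, p,
              dimnames = list(ids, sprintf("f%02d", seq_len(p))))
  X
}
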