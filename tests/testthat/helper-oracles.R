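# Independent reference implementations used as oracles. Deliberately
# naive/exhaustive: they share no code with the package internals.

# full three-matrix affine-gap local alignment DP (no rolling arrays)
sw_ref <- function(a, b, match = 2, mismatch = -1, open = 4, extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# enumerate the global alignments of two short sequences by memoized
# recursion over suffixes, carrying the (length, identical) pairs of every
# score-optimal suffix alignment; returns the best score and the set of
# identities attainable by optimal alignments
nw_enum <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  memo <- vector("list", (n + 2) * (m + 2))
  shift <- function(res, dscore, dlen, dident) {
    list(score = res$score + dscore,
         pairs = cbind(res$pairs[, 1] + dlen, res$pairs[, 2] + dident))
  }
  merge2 <- function(x, y) {
    if (is.null(x)) return(y)
    if (y$score > x$score) return(y)
    if (y$score < x$score) return(x)
    list(score = x$score,
         pairs = unique(rbind(x$pairs, y$pairs)))
  }
  rec <- function(i, j) {
    key <- i * (m + 2) + j + 1
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- NULL
    if (i > n && j > m) {
      out <- list(score = 0, pairs = cbind(0, 0))
    } else {
      if (i <= n && j <= m) {
        hit <- A[i] == B[j]
        out <- merge2(out, shift(rec(i + 1, j + 1),
                                 if (hit) match else mismatch, 1, hit))
      }
      if (i <= n) out <- merge2(out, shift(rec(i + 1, j), gap, 1, 0))
      if (j <= m) out <- merge2(out, shift(rec(i, j + 1), gap, 1, 0))
    }
    memo[[key]] <<- out
    out
  }
  res <- rec(1, 1)
  list(best = res$score,
       idents = unique(res$pairs[, 2] / res$pairs[, 1]))
}

# dense-matrix MCL iteration, independent of the sparse implementation
mcl_ref <- function(adj, inflation = 2, prune = 1e-5, max_iter = 100) {
  diag(adj) <- apply(adj, 1, max)
  normalize <- function(M) sweep(M, 2, pmax(colSums(M), .Machine$double.eps), "/")
  M <- normalize(adj)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    M2 <- normalize(M2)
    if (max(abs(M2 - M)) < 1e-9) {
      M <- M2
      break
    }
    M <- M2
  }
  supp <- (M + t(M)) > 0
  n <- nrow(adj)
  comp <- rep(0L, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0) next
    cid <- cid + 1L
    queue <- v
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      if (comp[u] > 0) next
      comp[u] <- cid
      queue <- c(queue, which(supp[u, ] & comp == 0))
    }
  }
  comp
}

# exact upper-tail hypergeometric probability by enumerating all draws of
# the study set from the population (n_pop <= 12)
hyper_enum <- function(n_pop, k_pop, n_study, k_study) {
  pop <- c(rep(1, k_pop), rep(0, n_pop - k_pop))
  draws <- utils::combn(n_pop, n_study)
  hits <- apply(draws, 2, function(ix) sum(pop[ix]))
  mean(hits >= k_study)
}

# hand step-up Benjamini-Hochberg
bh_ref <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- min(running, 1)
  }
  q
}

# exact one-sided Mann-Whitney p (x stochastically greater) by enumerating
# every assignment of the pooled values into the two groups
mwu_enum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  assigns <- utils::combn(length(pooled), n1)
  us <- apply(assigns, 2, u_of)
  mean(us >= u_obs)
}
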