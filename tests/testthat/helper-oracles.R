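# Independent oracles and small fixture builders, kept deliberately naive.

# literal sample-by-sample PLI, the definition written as a loop
brutePli <- function(pa, pb) {
  s <- 0
  for (k in seq_along(pa)) s <- s + sign(sin(pa[k] - pb[k]))
  abs(s / length(pa))
}

# channel c minus the mean of its neighbors, recomputed directly
bruteSourceDerivation <- function(x, labels, neighbors, lab) {
  x[lab, ] - colMeans(x[neighbors[[lab]], , drop = FALSE])
}

# decode a Prufer sequence into the edge list of a labelled tree
pruferDecode <- function(pruf, n) {
  deg <- rep(1L, n)
  for (v in pruf) deg[v] <- deg[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  ptr <- 0L
  for (v in pruf) {
    leaf <- which(deg == 1L)[1]
    ptr <- ptr + 1L
    edges[ptr, ] <- c(leaf, v)
    deg[leaf] <- deg[leaf] - 1L
    deg[v] <- deg[v] - 1L
  }
  rest <- which(deg == 1L)
  edges[n - 1L, ] <- rest
  edges
}

# maximum spanning-tree weight by exhaustive enumeration over all n^(n-2)
# labelled trees (Cayley)
exhaustiveMaxTreeWeight <- function(w) {
  n <- nrow(w)
  if (n == 2L) return(w[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    e <- pruferDecode(seqs[r, ], n)
    tw <- sum(w[e])
    if (tw > best) best <- tw
  }
  best
}

# betweenness on a tree by explicit path counting over all pairs,
# normalized to [0,1]
bruteTreeBetweenness <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  pathBetween <- function(s, t) {
    # DFS for the unique path s -> t
    stack <- list(s)
    prev <- rep(0L, n)
    seen <- rep(FALSE, n)
    seen[s] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (v == t) break
      for (u in adj[[v]]) if (!seen[u]) {
        seen[u] <- TRUE
        prev[u] <- v
        stack[[length(stack) + 1L]] <- u
      }
    }
    path <- t
    while (path[1] != s) path <- c(prev[path[1]], path)
    path
  }
  bc <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    p <- pathBetween(s, t)
    inner <- setdiff(p, c(s, t))
    bc[inner] <- bc[inner] + 1
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# a recording holding pure sinusoids, one frequency per channel
sineRecording <- function(freqs, durationS = 8, fs = 500, amp = 1,
                          phase = 0) {
  tt <- (seq_len(round(durationS * fs)) - 1) / fs
  x <- t(vapply(seq_along(freqs),
                function(k) amp * sin(2 * pi * freqs[k] * tt + phase),
                numeric(length(tt))))
  eegRecording(x, fs, sprintf("CH%02d", seq_along(freqs)))
}

# wrap a channels x time matrix as a one-epoch EpochSet
asEpochSet <- function(x, fs = 500) {
  extractEpochs(eegRecording(as.matrix(x), fs), ncol(as.matrix(x)) / fs, 1L)
}

# PLI of a two-channel recording from raw (unfiltered) analytic phases
rawPairPli <- function(rec) {
  x <- samples(rec)
  fs <- samplingRate(rec)
  p1 <- instantaneousPhase(x[1, ], fs)
  p2 <- instantaneousPhase(x[2, ], fs)
  m <- attr(p1, "edgeMargin")
  n <- length(p1)
  pliPair(p1[(m + 1):(n - m)], p2[(m + 1):(n - m)])
}

# random symmetric non-negative matrix with zero diagonal
randomSymmetric <- function(n) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2)
  w + t(w)
}
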