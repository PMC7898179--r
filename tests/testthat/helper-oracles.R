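# Brute-force oracles used by several test files.

# enumerate every labelled spanning tree via Pruefer sequences (n^(n-2) trees)
pruefer_tree_edges <- function(seq, n) {
  degree <- rep(1L, n)
  for (v in seq) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  for (i in seq_along(seq)) {
    leaf <- min(which(degree == 1L))
    edges[i, ] <- c(leaf, seq[i])
    degree[leaf] <- degree[leaf] - 1L
    degree[seq[i]] <- degree[seq[i]] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}

min_spanning_length <- function(d) {
  n <- nrow(d)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- pruefer_tree_edges(seqs[i, ], n)
    best <- min(best, sum(d[cbind(e[, 1], e[, 2])]))
  }
  best
}
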