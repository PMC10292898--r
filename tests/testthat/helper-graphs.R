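# Small graph constructors used across tests.

edgesDf <- function(a, b) data.frame(a = a, b = b, stringsAsFactors = FALSE)

pathEdges <- function(ids) edgesDf(ids[-length(ids)], ids[-1L])

starEdges <- function(center, leaves) edgesDf(rep(center, length(leaves)), leaves)

cycleEdges <- function(ids) edgesDf(ids, c(ids[-1L], ids[1L]))

completeEdges <- function(ids) {
  p <- t(utils::combn(ids, 2L))
  edgesDf(p[, 1L], p[, 2L])
}

disjointEdges <- function(n, prefix = "D") {
  edgesDf(sprintf("%sA%03d", prefix, seq_len(n)),
          sprintf("%sB%03d", prefix, seq_len(n)))
}

# Erdos-Renyi random edge list (kept connected enough by rejecting empties).
randomEdges <- function(nNodes, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(nNodes))
  pairs <- t(utils::combn(nodes, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  if (sum(keep) < 2L) keep[sample.int(length(keep), 2L)] <- TRUE
  edgesDf(pairs[keep, 1L], pairs[keep, 2L])
}
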