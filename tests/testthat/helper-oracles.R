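# Brute-force oracles, deliberately independent of the package's (igraph)
# graph machinery: Floyd-Warshall all-pairs distances, flood-fill components,
# and pair-counting AUC.

oracleDistances <- function(edges, nodes) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges[[1L]][i]; b <- edges[[2L]][i]
    if (a != b) D[a, b] <- D[b, a] <- 1
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

oracleComponents <- function(edges, nodes) {
  comp <- seq_along(nodes)
  names(comp) <- nodes
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges[[1L]][i]; b <- edges[[2L]][i]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[a] <- comp[b] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

oracleLCCSize <- function(edges, nodes, restrict = NULL) {
  if (!is.null(restrict)) {
    nodes <- intersect(nodes, restrict)
    keep <- edges[[1L]] %in% nodes & edges[[2L]] %in% nodes
    edges <- edges[keep, , drop = FALSE]
  }
  if (length(nodes) == 0L) return(0L)
  comp <- oracleComponents(edges, nodes)
  max(table(comp))
}

oracleClosest <- function(D, S, T) {
  mean(apply(D[T, S, drop = FALSE], 1L, min))
}

oracleShortest <- function(D, S, T) {
  mean(D[T, S, drop = FALSE])
}

oracleAuc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Exhaustive enumeration of all degree-matched replacement sets for `target`
# under `bins` (cartesian product of within-bin combinations).
enumDegreeMatched <- function(target, bins) {
  idx <- bins@binIndex[target]
  counts <- tabulate(idx, nbins = length(bins@binMembers))
  perBin <- lapply(seq_along(counts), function(b) {
    if (counts[b] == 0L) return(list(character(0)))
    utils::combn(bins@binMembers[[b]], counts[b], simplify = FALSE)
  })
  out <- list(character(0))
  for (b in seq_along(perBin)) {
    out <- unlist(lapply(out, function(base) {
      lapply(perBin[[b]], function(add) c(base, add))
    }), recursive = FALSE)
  }
  out
}
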