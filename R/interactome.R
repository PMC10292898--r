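# Construction and queries of the protein-protein interaction graph. All
# network distances downstream are unweighted hop counts on this graph.

#' Build an interactome from raw edge records
#'
#' Edge records are canonicalized (IDs uppercased and whitespace-stripped),
#' self-loops are dropped, and duplicate edges -- regardless of endpoint
#' order -- are collapsed to one, merging their source tags. Counts of
#' everything dropped or collapsed are kept in the load report.
#'
#' @param edgeRecords a data.frame (or 2--3 column matrix) whose first two
#'   columns are interacting protein IDs and whose optional third column is a
#'   source/provenance tag.
#' @return an \linkS4class{Interactome}.
#' @examples
#' g <- buildInteractome(data.frame(
#'   a = c("A", "B", "A", "B"), b = c("B", "A", "A", "C")))
#' loadReport(g)
#' @export
buildInteractome <- function(edgeRecords) {
  if (is.matrix(edgeRecords)) edgeRecords <- as.data.frame(edgeRecords)
  if (!is.data.frame(edgeRecords) || nrow(edgeRecords) == 0L) {
    stop("no edges")
  }
  if (ncol(edgeRecords) < 2L) stop("edge records need two ID columns")
  a <- canonicalizeIds(edgeRecords[[1L]])
  b <- canonicalizeIds(edgeRecords[[2L]])
  .checkIdsNonEmpty(a, "protein_a")
  .checkIdsNonEmpty(b, "protein_b")
  src <- if (ncol(edgeRecords) >= 3L) as.character(edgeRecords[[3L]]) else NULL

  self <- a == b
  nSelf <- sum(self)
  a2 <- a[!self]; b2 <- b[!self]
  if (length(a2) == 0L) stop("no edges left after dropping self-loops")
  lo <- pmin(a2, b2)
  hi <- pmax(a2, b2)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  nDup <- sum(dup)

  edges <- data.frame(from = lo[!dup], to = hi[!dup],
                      stringsAsFactors = FALSE)
  if (!is.null(src)) {
    src2 <- src[!self]
    tags <- vapply(split(src2, key), function(s) {
      s <- unique(s[!is.na(s) & nzchar(s)])
      paste(sort(s), collapse = ",")
    }, character(1L))
    edges$sources <- unname(tags[key[!dup]])
  }

  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  obj <- new("Interactome", graph = g,
             loadReport = list(nRecords = nrow(edgeRecords),
                               nSelfLoopsDropped = as.integer(nSelf),
                               nDuplicatesCollapsed = as.integer(nDup),
                               nEdges = as.integer(igraph::ecount(g)),
                               nNodes = as.integer(igraph::vcount(g))))
  methods::validObject(obj)
  obj
}

# Internal: wrap an igraph object that already satisfies the invariants.
.asInteractome <- function(g, report = list()) {
  rep0 <- list(nRecords = as.integer(igraph::ecount(g)),
               nSelfLoopsDropped = 0L, nDuplicatesCollapsed = 0L,
               nEdges = as.integer(igraph::ecount(g)),
               nNodes = as.integer(igraph::vcount(g)))
  rep0[names(report)] <- report
  new("Interactome", graph = g, loadReport = rep0)
}

#' Interactome induced on a node subset
#'
#' @param g an \linkS4class{Interactome}.
#' @param ids node IDs to keep; IDs absent from the graph are ignored.
#' @return an \linkS4class{Interactome} on \code{ids} intersected with the
#'   nodes of \code{g}.
#' @export
inducedInteractome <- function(g, ids) {
  stopifnot(methods::is(g, "Interactome"))
  keep <- intersect(.asMembers(ids), nodeIds(g))
  sub <- igraph::induced_subgraph(g@graph, keep)
  .asInteractome(sub)
}

#' Subgraph of the interactome induced on a disease protein set
#'
#' @param g an \linkS4class{Interactome}.
#' @param disease a \linkS4class{TargetSet} (or character vector) of disease
#'   proteins.
#' @return an \linkS4class{Interactome} restricted to the disease proteins.
#' @export
diseaseSubgraph <- function(g, disease) {
  inducedInteractome(g, disease)
}

#' Largest connected component, optionally of an induced subgraph
#'
#' Returns the maximum-cardinality connected component of the subgraph induced
#' on \code{restrictTo} (or of the whole graph). Size ties are broken in favor
#' of the component containing the lexicographically smallest member ID.
#'
#' @param g an \linkS4class{Interactome}.
#' @param restrictTo optional node IDs (or a \linkS4class{TargetSet}); IDs
#'   absent from the graph are ignored, and a restriction disjoint from the
#'   graph yields a size-0 component.
#' @return a \linkS4class{ComponentView}.
#' @examples
#' g <- buildInteractome(data.frame(a = c("A", "B", "D"), b = c("B", "C", "E")))
#' componentSize(largestConnectedComponent(g))            # 3 (A-B-C)
#' componentSize(largestConnectedComponent(g, c("A", "C", "D", "E")))  # 2
#' @export
largestConnectedComponent <- function(g, restrictTo = NULL) {
  stopifnot(methods::is(g, "Interactome"))
  if (nodeCount(g) == 0L) stop("empty interactome")
  if (is.null(restrictTo)) {
    keep <- nodeIds(g)
  } else {
    keep <- intersect(.asMembers(restrictTo), nodeIds(g))
  }
  if (length(keep) == 0L) {
    return(new("ComponentView", parent = g, members = character(0),
               size = 0L))
  }
  sub <- igraph::induced_subgraph(g@graph, keep)
  comp <- igraph::components(sub)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    mins <- vapply(best, function(k) {
      min(igraph::V(sub)$name[comp$membership == k])
    }, character(1L))
    best <- best[order(mins)][1L]
  }
  mem <- sort(igraph::V(sub)$name[comp$membership == best])
  new("ComponentView", parent = g, members = mem, size = length(mem))
}

#' Multi-source breadth-first shortest path lengths
#'
#' Unweighted hop distances from the nearest of a set of source nodes. Nodes
#' unreachable from every source are absent from the result.
#'
#' @param g an \linkS4class{Interactome}.
#' @param sources node IDs; must all be present in the graph.
#' @return named integer vector of hop counts; every source maps to 0.
#' @examples
#' g <- buildInteractome(data.frame(a = c("A", "B", "C"), b = c("B", "C", "D")))
#' shortestPathLengthsFrom(g, c("A", "D"))
#' @export
shortestPathLengthsFrom <- function(g, sources) {
  stopifnot(methods::is(g, "Interactome"))
  sources <- .asMembers(sources)
  if (length(sources) == 0L) stop("empty source set")
  missing <- setdiff(sources, nodeIds(g))
  if (length(missing) > 0L) {
    stop("sources not in interactome: ", paste(utils::head(missing, 5L),
                                               collapse = ", "))
  }
  D <- igraph::distances(g@graph, v = sources)
  d <- .rowMins(t(D))
  d <- d[is.finite(d)]
  storage.mode(d) <- "integer"
  d
}

#' Restrict an interactome to its largest connected component
#'
#' Network proximity needs finite distances between all analyzed node pairs,
#' so analyses run on the interactome's own largest connected component;
#' nodes outside it are dropped with a message.
#'
#' @param g an \linkS4class{Interactome}.
#' @return an \linkS4class{Interactome} on the largest component; the load
#'   report records how many nodes were dropped.
#' @export
analysisComponent <- function(g) {
  stopifnot(methods::is(g, "Interactome"))
  lcc <- largestConnectedComponent(g)
  dropped <- nodeCount(g) - componentSize(lcc)
  if (dropped > 0L) {
    message("analysisComponent: dropping ", dropped,
            " node(s) outside the largest connected component")
  }
  out <- inducedInteractome(g, members(lcc))
  out@loadReport$nNodesOutsideLCC <- dropped
  out
}

#' Edge table of an interactome
#'
#' @param g an \linkS4class{Interactome}.
#' @return data.frame with columns \code{protein_a}, \code{protein_b} and,
#'   when present, \code{source}.
#' @export
edgeTable <- function(g) {
  stopifnot(methods::is(g, "Interactome"))
  el <- igraph::as_edgelist(g@graph)
  out <- data.frame(protein_a = el[, 1L], protein_b = el[, 2L],
                    stringsAsFactors = FALSE)
  if ("sources" %in% igraph::edge_attr_names(g@graph)) {
    out$source <- igraph::E(g@graph)$sources
  }
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
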