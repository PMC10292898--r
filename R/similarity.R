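# Target-set overlap. Compounds of a multi-compound natural product typically
# share few targets; the Jaccard index quantifies that before any network
# analysis is attempted.

#' Jaccard index between two target sets
#'
#' \eqn{J(A, B) = |A \cap B| / |A \cup B|}.
#'
#' @param a,b \linkS4class{TargetSet}s (or character vectors of IDs).
#' @return a number in [0, 1].
#' @examples
#' jaccardIndex(c("G1", "G2"), c("G2", "G3"))  # 1/3
#' @export
jaccardIndex <- function(a, b) {
  ma <- .asMembers(a)
  mb <- .asMembers(b)
  if (length(ma) == 0L || length(mb) == 0L) stop("empty target set")
  length(intersect(ma, mb)) / length(union(ma, mb))
}

#' Pairwise Jaccard similarity over a collection of target sets
#'
#' The summary statistic \code{meanOffdiag} averages the strict upper
#' triangle: distinct pairs only, so the unit self-similarities cannot
#' inflate it.
#'
#' @param sets list of \linkS4class{TargetSet}s with unique names (at least
#'   two).
#' @return a \linkS4class{SimilarityMatrix}.
#' @examples
#' sets <- list(TargetSet("c1", c("G1", "G2")), TargetSet("c2", c("G2", "G3")))
#' meanOffdiag(pairwiseJaccard(sets))
#' @export
pairwiseJaccard <- function(sets) {
  if (length(sets) < 2L) stop("need at least two target sets")
  nms <- vapply(sets, setName, character(1L))
  if (anyDuplicated(nms)) stop("duplicate set names")
  n <- length(sets)
  v <- diag(nrow = n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      v[i, j] <- v[j, i] <- jaccardIndex(sets[[i]], sets[[j]])
    }
  }
  new("SimilarityMatrix", names = nms, values = v,
      meanOffdiag = mean(v[upper.tri(v)]))
}

#' Write a similarity matrix as TSV plus a JSON summary
#'
#' @param sm a \linkS4class{SimilarityMatrix}.
#' @param tsvPath path for the matrix TSV.
#' @param jsonPath optional path for a JSON summary (set count, mean
#'   off-diagonal Jaccard).
#' @return invisibly, \code{tsvPath}.
#' @export
writeSimilarity <- function(sm, tsvPath, jsonPath = NULL) {
  v <- similarityValues(sm)
  utils::write.table(data.frame(set = rownames(v), v, check.names = FALSE),
                     tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(jsonPath)) {
    .writeJSON(list(nSets = length(sm@names), meanOffdiagJaccard = sm@meanOffdiag),
               jsonPath)
  }
  invisible(tsvPath)
}
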