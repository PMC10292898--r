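# Disease-module significance: does a compound's target set form a larger
# connected component than degree-matched chance?

#' LCC size and significance of a compound's targets
#'
#' Computes the size of the largest connected component induced by the
#' compound's targets in \code{g} and compares it to the LCC sizes of
#' \code{nReps} degree-matched random node sets of the same size. The
#' screening rule follows the |z| > 1.70 convention.
#'
#' @param g the analysis \linkS4class{Interactome} (the full interactome's
#'   largest component for a global analysis, or the disease-protein-induced
#'   subgraph for a disease-restricted one; \code{bins} must be built on the
#'   same graph).
#' @param targets a \linkS4class{TargetSet} (or character vector).
#' @param bins \linkS4class{DegreeBins} on \code{g}.
#' @param nReps null replicates (default 1000).
#' @param zThreshold significance threshold on |z| (default 1.70).
#' @param seed optional seed for the null replicates.
#' @param minTargets minimum mapped targets to evaluate (default 2: a
#'   connected component needs two nodes).
#' @return an \linkS4class{LCCResult}; compounds with fewer than
#'   \code{minTargets} mapped targets are flagged \code{"not_evaluated"},
#'   and a zero-variance null is flagged \code{"degenerate_null"} (z = 0
#'   when observed equals the null mean, signed infinity otherwise).
#' @examples
#' g <- generateInteractome(syntheticScenario(seed = 1, nNodes = 300))
#' bins <- makeDegreeBins(g, minBinSize = 50)
#' mod <- plantDiseaseModule(g, syntheticScenario(seed = 1, nNodes = 300,
#'                                                moduleSize = 12))
#' lccZScore(g, mod, bins, nReps = 100, seed = 7)
#' @export
lccZScore <- function(g, targets, bins, nReps = 1000L, zThreshold = 1.70,
                      seed = NULL, minTargets = 2L) {
  stopifnot(methods::is(g, "Interactome"))
  compound <- if (methods::is(targets, "TargetSet")) setName(targets) else "targets"
  mem <- .asMembers(targets)
  mapped <- intersect(mem, nodeIds(g))
  if (length(mapped) < length(mem)) {
    message("lccZScore('", compound, "'): ", length(mem) - length(mapped),
            " target(s) not in the analysis graph")
  }
  if (length(mapped) < minTargets) {
    return(new("LCCResult", compound = compound,
               nTargetsMapped = length(mapped),
               lccSize = as.integer(length(mapped) > 0L),
               null = .NullDistribution(numeric(1L), seed),
               z = NA_real_, significant = FALSE, flag = "not_evaluated"))
  }
  lcc <- componentSize(largestConnectedComponent(g, mapped))
  gg <- g@graph
  sizes <- .nullReplicates(mapped, bins, nReps, seed, function(ids) {
    max(igraph::components(igraph::induced_subgraph(gg, ids))$csize)
  })
  null <- .NullDistribution(sizes, seed)
  zres <- .zAgainstNull(lcc, null)
  new("LCCResult", compound = compound, nTargetsMapped = length(mapped),
      lccSize = as.integer(lcc), null = null, z = zres$z,
      significant = is.finite(zres$z) && abs(zres$z) > zThreshold ||
        is.infinite(zres$z),
      flag = zres$flag)
}

#' Screen LCC results for significant compounds
#'
#' @param results list of \linkS4class{LCCResult}s.
#' @return character vector of significant compound names, sorted by |z|
#'   descending (infinite z first).
#' @export
screenSignificant <- function(results) {
  if (length(results) == 0L) return(character(0))
  sig <- vapply(results, function(r) isTRUE(r@significant), logical(1L))
  res <- results[sig]
  if (length(res) == 0L) return(character(0))
  az <- vapply(res, function(r) abs(r@z), numeric(1L))
  vapply(res[order(-az)], function(r) r@compound, character(1L))
}

#' Tabulate LCC results
#'
#' @param results list of \linkS4class{LCCResult}s.
#' @return data.frame: compound, n_targets, lcc_size, mu, sigma, z,
#'   significant, flag.
#' @export
lccTable <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(compound = r@compound, n_targets = r@nTargetsMapped,
               lcc_size = r@lccSize, mu = r@null@mu, sigma = r@null@sigma,
               z = r@z, significant = r@significant, flag = r@flag,
               stringsAsFactors = FALSE)
  }))
}
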