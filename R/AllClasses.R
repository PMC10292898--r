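#' @import methods
NULL

#' Interactome: an undirected, unweighted protein-protein interaction graph
#'
#' Wraps an \pkg{igraph} graph with the invariants every downstream analysis
#' relies on: no self-loops, no duplicate edges, canonical (uppercase,
#' whitespace-stripped) node identifiers, and a load report recording what was
#' dropped or collapsed during construction. Build one with
#' \code{\link{buildInteractome}} or \code{\link{readEdgeList}}.
#'
#' @slot graph an undirected \code{igraph} object with named vertices.
#' @slot loadReport list of construction counts (input records, self-loops
#'   dropped, duplicates collapsed, final node/edge counts).
#' @aliases Interactome
#' @exportClass Interactome
setClass("Interactome",
  slots = c(graph = "ANY", loadReport = "list"))

setValidity("Interactome", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (igraph::is_directed(g)) return("interactome must be undirected")
  if (igraph::any_loop(g)) return("self-loops are not allowed")
  if (igraph::any_multiple(g)) return("duplicate edges are not allowed")
  nm <- igraph::V(g)$name
  if (is.null(nm)) return("vertices must be named")
  if (anyDuplicated(nm)) return("duplicate node IDs")
  if (any(is.na(nm) | !nzchar(nm))) return("empty node IDs")
  if (!identical(nm, canonicalizeIds(nm))) {
    return("node IDs must be uppercase and whitespace-stripped")
  }
  TRUE
})

#' TargetSet: a named set of protein identifiers
#'
#' Holds one compound's targets or a disease protein set, with identifiers in
#' canonical form.
#'
#' @slot name label of the compound or disease.
#' @slot members unique canonical protein IDs; never empty.
#' @aliases TargetSet-class
#' @exportClass TargetSet
setClass("TargetSet",
  slots = c(name = "character", members = "character"))

setValidity("TargetSet", function(object) {
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name)) {
    return("name must be a single non-empty string")
  }
  m <- object@members
  if (length(m) == 0L) return("members must be non-empty")
  if (any(is.na(m) | !nzchar(m))) return("empty member IDs")
  if (anyDuplicated(m)) return("duplicate member IDs")
  if (!identical(m, canonicalizeIds(m))) return("member IDs not canonical")
  TRUE
})

#' Construct a TargetSet
#'
#' @param name compound or disease label.
#' @param members character vector of protein IDs; canonicalized (uppercase,
#'   stripped) and de-duplicated.
#' @return a \linkS4class{TargetSet}.
#' @examples
#' TargetSet("quercetin", c("akt1", " TP53", "AKT1"))
#' @export
TargetSet <- function(name, members) {
  m <- unique(canonicalizeIds(members))
  m <- m[nzchar(m) & !is.na(m)]
  if (length(m) == 0L) stop("target set '", name, "' is empty")
  new("TargetSet", name = as.character(name), members = m)
}

#' ComponentView: one connected component of an induced subgraph
#'
#' @slot parent the \linkS4class{Interactome} the component lives in.
#' @slot members node IDs of the component (sorted).
#' @slot size number of member nodes.
#' @exportClass ComponentView
setClass("ComponentView",
  slots = c(parent = "Interactome", members = "character", size = "integer"))

setValidity("ComponentView", function(object) {
  if (object@size != length(object@members)) return("size != |members|")
  if (object@size > 0L) {
    g <- object@parent@graph
    if (!all(object@members %in% igraph::V(g)$name)) {
      return("members not in parent interactome")
    }
    sub <- igraph::induced_subgraph(g, object@members)
    if (!igraph::is_connected(sub)) return("members do not induce a connected subgraph")
  }
  TRUE
})

#' SimilarityMatrix: pairwise Jaccard indices between target sets
#'
#' @slot names ordered set labels.
#' @slot values symmetric matrix of Jaccard indices in [0, 1], unit diagonal.
#' @slot meanOffdiag mean over the strict upper triangle.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  slots = c(names = "character", values = "matrix", meanOffdiag = "numeric"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  n <- length(object@names)
  if (!all(dim(v) == c(n, n))) return("matrix dimensions disagree with names")
  if (any(v < 0 | v > 1)) return("Jaccard values outside [0, 1]")
  if (!isTRUE(all.equal(v, t(v)))) return("matrix not symmetric")
  if (!isTRUE(all.equal(unname(diag(v)), rep(1, n)))) return("diagonal not 1")
  TRUE
})

#' DegreeBins: degree-stratified partition of interactome nodes
#'
#' Nodes are grouped by degree into bins of at least \code{minBinSize} members
#' (greedy merge from the lowest degree upward); random degree-matched samples
#' are drawn within bins so that hubs are not resampled into every replicate.
#'
#' @slot binMembers list of character vectors, one per bin.
#' @slot binIndex named integer: node ID to bin number.
#' @slot binRanges data.frame with columns lower, upper, size.
#' @slot minBinSize requested minimum bin occupancy.
#' @exportClass DegreeBins
setClass("DegreeBins",
  slots = c(binMembers = "list", binIndex = "integer",
            binRanges = "data.frame", minBinSize = "integer"))

setValidity("DegreeBins", function(object) {
  sizes <- lengths(object@binMembers)
  if (sum(sizes) != length(object@binIndex)) return("bins do not partition nodes")
  if (length(sizes) > 1L && any(sizes < object@minBinSize)) {
    return("undersized bin in a multi-bin partition")
  }
  idx <- object@binIndex
  for (b in seq_along(object@binMembers)) {
    if (!setequal(object@binMembers[[b]], names(idx)[idx == b])) {
      return("binIndex inconsistent with binMembers")
    }
  }
  TRUE
})

#' NullDistribution: replicate statistics of a degree-preserving null
#'
#' @slot values statistic value of each random replicate.
#' @slot mu mean of the replicates.
#' @slot sigma sample standard deviation of the replicates.
#' @slot nReps number of replicates.
#' @slot seed seed the replicates were drawn under (NA if none).
#' @exportClass NullDistribution
setClass("NullDistribution",
  slots = c(values = "numeric", mu = "numeric", sigma = "numeric",
            nReps = "integer", seed = "integer"))

setValidity("NullDistribution", function(object) {
  if (object@nReps != length(object@values)) return("nReps != length(values)")
  if (!isTRUE(all.equal(object@mu, mean(object@values)))) return("mu not recomputable")
  sig <- stats::sd(object@values)
  if (object@nReps > 1L && !isTRUE(all.equal(object@sigma, sig))) {
    return("sigma not recomputable")
  }
  TRUE
})

.NullDistribution <- function(values, seed = NA_integer_) {
  values <- as.numeric(values)
  new("NullDistribution", values = values, mu = mean(values),
      sigma = if (length(values) > 1L) stats::sd(values) else 0,
      nReps = length(values),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' LCCResult: largest-connected-component significance for one compound
#'
#' @slot compound compound label.
#' @slot nTargetsMapped targets found in the analysis graph.
#' @slot lccSize size of the largest connected component they induce.
#' @slot null degree-preserving \linkS4class{NullDistribution} of LCC sizes.
#' @slot z (lccSize - mu) / sigma.
#' @slot significant TRUE when |z| exceeds the screening threshold.
#' @slot flag "ok", "not_evaluated" (fewer than the minimum mapped targets) or
#'   "degenerate_null" (sigma == 0).
#' @exportClass LCCResult
setClass("LCCResult",
  slots = c(compound = "character", nTargetsMapped = "integer",
            lccSize = "integer", null = "NullDistribution", z = "numeric",
            significant = "logical", flag = "character"))

setValidity("LCCResult", function(object) {
  if (object@lccSize > object@nTargetsMapped) return("lccSize > nTargetsMapped")
  TRUE
})

#' ProximityResult: network proximity of one compound to a disease set
#'
#' @slot compound compound label.
#' @slot nS,nT mapped compound-target / disease-protein counts.
#' @slot dClosest mean over disease proteins of the hop distance to the
#'   nearest compound target.
#' @slot dShortest mean over all (target, disease protein) pairs.
#' @slot zClosest,zShortest z-scores against degree-preserving nulls (NA when
#'   the metric was not computed).
#' @slot nullClosest,nullShortest the backing \linkS4class{NullDistribution}s
#'   (or NULL).
#' @slot flag "ok" or "degenerate_null".
#' @exportClass ProximityResult
setClass("ProximityResult",
  slots = c(compound = "character", nS = "integer", nT = "integer",
            dClosest = "numeric", dShortest = "numeric",
            zClosest = "numeric", zShortest = "numeric",
            nullClosest = "ANY", nullShortest = "ANY", flag = "character"))

#' ROCResult: receiver operating characteristic summary
#'
#' @slot auc area under the curve (pair-counting; ties count 0.5).
#' @slot nPos,nNeg class counts.
#' @slot curve data.frame of (fpr, tpr) from (0,0) to (1,1).
#' @slot compareP optional p-value from an AUC comparison (NA otherwise).
#' @exportClass ROCResult
setClass("ROCResult",
  slots = c(auc = "numeric", nPos = "integer", nNeg = "integer",
            curve = "data.frame", compareP = "numeric"))

setValidity("ROCResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc outside [0, 1]")
  cv <- object@curve
  if (nrow(cv) > 0L) {
    if (any(diff(cv$fpr) < 0) || any(diff(cv$tpr) < 0)) {
      return("curve coordinates must be non-decreasing")
    }
  }
  TRUE
})

#' DiagnosticResult: per-gene diagnostic ROC with Youden cutoff
#'
#' @slot gene gene ID.
#' @slot auc orientation-corrected AUC (always >= 0.5 unless degenerate).
#' @slot cutoff expression value maximizing Youden's J (NA when degenerate).
#' @slot sensAtCutoff,specAtCutoff sensitivity / specificity at the cutoff.
#' @slot highAccuracy TRUE when auc > 0.9.
#' @slot direction "up" (high expression marks cases) or "down".
#' @slot flag "ok" or "constant_expression".
#' @exportClass DiagnosticResult
setClass("DiagnosticResult",
  slots = c(gene = "character", auc = "numeric", cutoff = "numeric",
            sensAtCutoff = "numeric", specAtCutoff = "numeric",
            highAccuracy = "logical", direction = "character",
            flag = "character"))

#' SyntheticScenario: parameters of the synthetic study generator
#'
#' Defaults emulate the shape of the study the pipeline is designed for: a
#' scale-free interactome with one dominant component, a connected planted
#' disease module, ~30 compounds of ~10 targets each of which a few are
#' signal compounds overlapping the module neighborhood, and a two-group
#' expression matrix of 26 + 26 samples with a planted fraction of
#' differentially expressed genes.
#'
#' @slot seed master seed; every random stage derives its own stream from it.
#' @slot nNodes interactome size (preferential-attachment growth).
#' @slot attachment edges added per new node.
#' @slot moduleSize size of the connected planted disease module.
#' @slot nSignal,nNull signal / null compound counts.
#' @slot targetsPerCompound targets per compound.
#' @slot overlapFraction fraction of a signal compound's targets drawn from
#'   the module and its first neighbors.
#' @slot nGenes,nPerGroup expression matrix dimensions (genes, samples per group).
#' @slot deFraction fraction of genes differentially expressed.
#' @slot effectLogFC planted absolute log2 fold change.
#' @slot noiseSd Gaussian noise standard deviation.
#' @exportClass SyntheticScenario
setClass("SyntheticScenario",
  slots = c(seed = "integer", nNodes = "integer", attachment = "integer",
            moduleSize = "integer", nSignal = "integer", nNull = "integer",
            targetsPerCompound = "integer", overlapFraction = "numeric",
            nGenes = "integer", nPerGroup = "integer", deFraction = "numeric",
            effectLogFC = "numeric", noiseSd = "numeric"))

setValidity("SyntheticScenario", function(object) {
  counts <- c(object@nNodes, object@attachment, object@moduleSize,
              object@nSignal + object@nNull, object@targetsPerCompound,
              object@nGenes, object@nPerGroup)
  if (any(counts <= 0L)) return("all counts must be positive")
  fr <- c(object@overlapFraction, object@deFraction)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  if (object@nNodes < 10L) return("nNodes must be at least 10")
  if (object@moduleSize >= object@nNodes) return("module larger than graph")
  if (object@noiseSd <= 0) return("noiseSd must be positive")
  TRUE
})

#' Construct a SyntheticScenario
#'
#' @param seed master seed (integer).
#' @param nNodes,attachment,moduleSize,nSignal,nNull,targetsPerCompound,
#'   overlapFraction,nGenes,nPerGroup,deFraction,effectLogFC,noiseSd see
#'   \linkS4class{SyntheticScenario}.
#' @return a \linkS4class{SyntheticScenario}.
#' @examples
#' syntheticScenario(seed = 1, nNodes = 300, moduleSize = 15)
#' @export
syntheticScenario <- function(seed = 1L, nNodes = 2000L, attachment = 2L,
                              moduleSize = 30L, nSignal = 3L, nNull = 27L,
                              targetsPerCompound = 10L, overlapFraction = 0.7,
                              nGenes = 1000L, nPerGroup = 26L,
                              deFraction = 0.1, effectLogFC = 2.0,
                              noiseSd = 0.5) {
  new("SyntheticScenario", seed = as.integer(seed), nNodes = as.integer(nNodes),
      attachment = as.integer(attachment), moduleSize = as.integer(moduleSize),
      nSignal = as.integer(nSignal), nNull = as.integer(nNull),
      targetsPerCompound = as.integer(targetsPerCompound),
      overlapFraction = overlapFraction, nGenes = as.integer(nGenes),
      nPerGroup = as.integer(nPerGroup), deFraction = deFraction,
      effectLogFC = effectLogFC, noiseSd = noiseSd)
}
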