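# Generics and accessor/show methods for the package's S4 classes.

#' @name accessors
#' @title Accessors for netRepurpose objects
#' @description Slot access for the package's S4 classes goes through these
#'   accessors; slots are implementation detail.
#' @param x an object of the documented class.
#' @return the accessed component.
#' @examples
#' g <- buildInteractome(data.frame(a = c("A", "B"), b = c("B", "C")))
#' nodeIds(g); nodeCount(g); edgeCount(g); nodeDegrees(g)
NULL

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname accessors
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))
#' @rdname accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @rdname accessors
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))
#' @rdname accessors
#' @export
setGeneric("loadReport", function(x) standardGeneric("loadReport"))
#' @rdname accessors
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("componentSize", function(x) standardGeneric("componentSize"))
#' @rdname accessors
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
#' @rdname accessors
#' @export
setGeneric("meanOffdiag", function(x) standardGeneric("meanOffdiag"))
#' @rdname accessors
#' @export
setGeneric("replicateValues", function(x) standardGeneric("replicateValues"))
#' @rdname accessors
#' @export
setGeneric("nullMean", function(x) standardGeneric("nullMean"))
#' @rdname accessors
#' @export
setGeneric("nullSd", function(x) standardGeneric("nullSd"))
#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname accessors
setMethod("nodeIds", "Interactome", function(x) igraph::V(x@graph)$name)
#' @rdname accessors
setMethod("nodeCount", "Interactome", function(x) as.integer(igraph::vcount(x@graph)))
#' @rdname accessors
setMethod("edgeCount", "Interactome", function(x) as.integer(igraph::ecount(x@graph)))
#' @rdname accessors
setMethod("nodeDegrees", "Interactome", function(x) {
  d <- igraph::degree(x@graph)
  storage.mode(d) <- "integer"
  d
})
#' @rdname accessors
setMethod("loadReport", "Interactome", function(x) x@loadReport)

#' @rdname accessors
setMethod("setName", "TargetSet", function(x) x@name)
#' @rdname accessors
setMethod("members", "TargetSet", function(x) x@members)
#' @rdname accessors
setMethod("members", "ComponentView", function(x) x@members)
#' @rdname accessors
setMethod("componentSize", "ComponentView", function(x) x@size)

#' @rdname accessors
setMethod("similarityValues", "SimilarityMatrix", function(x) {
  v <- x@values
  dimnames(v) <- list(x@names, x@names)
  v
})
#' @rdname accessors
setMethod("meanOffdiag", "SimilarityMatrix", function(x) x@meanOffdiag)

#' @rdname accessors
setMethod("replicateValues", "NullDistribution", function(x) x@values)
#' @rdname accessors
setMethod("nullMean", "NullDistribution", function(x) x@mu)
#' @rdname accessors
setMethod("nullSd", "NullDistribution", function(x) x@sigma)

#' @rdname accessors
setMethod("aucValue", "ROCResult", function(x) x@auc)
#' @rdname accessors
setMethod("aucValue", "DiagnosticResult", function(x) x@auc)

setMethod("show", "Interactome", function(object) {
  cat("Interactome with", nodeCount(object), "proteins and",
      edgeCount(object), "interactions\n")
  rep <- object@loadReport
  if (length(rep)) {
    cat("  load: ", rep$nRecords, " records, ",
        rep$nSelfLoopsDropped, " self-loops dropped, ",
        rep$nDuplicatesCollapsed, " duplicates collapsed\n", sep = "")
  }
})

setMethod("show", "TargetSet", function(object) {
  cat("TargetSet '", object@name, "' with ", length(object@members),
      " members\n", sep = "")
})

setMethod("show", "ComponentView", function(object) {
  cat("ComponentView of size", object@size, "\n")
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix over", length(object@names),
      "sets; mean off-diagonal Jaccard =",
      format(object@meanOffdiag, digits = 4), "\n")
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution:", object@nReps, "replicates, mu =",
      format(object@mu, digits = 4), ", sigma =",
      format(object@sigma, digits = 4), "\n")
})

setMethod("show", "LCCResult", function(object) {
  cat("LCCResult '", object@compound, "': lcc = ", object@lccSize, "/",
      object@nTargetsMapped, " targets, z = ", format(object@z, digits = 4),
      ", significant = ", object@significant,
      if (object@flag != "ok") paste0(" [", object@flag, "]") else "",
      "\n", sep = "")
})

setMethod("show", "ProximityResult", function(object) {
  cat("ProximityResult '", object@compound, "': d_closest = ",
      format(object@dClosest, digits = 4), " (z = ",
      format(object@zClosest, digits = 4), "), d_shortest = ",
      format(object@dShortest, digits = 4), " (z = ",
      format(object@zShortest, digits = 4), ")\n", sep = "")
})

setMethod("show", "ROCResult", function(object) {
  cat("ROCResult: AUC = ", format(object@auc, digits = 4), " (",
      object@nPos, " positives, ", object@nNeg, " negatives)",
      if (!is.na(object@compareP)) {
        paste0(", comparison p = ", format(object@compareP, digits = 4))
      } else "",
      "\n", sep = "")
})

setMethod("show", "DiagnosticResult", function(object) {
  cat("DiagnosticResult '", object@gene, "': AUC = ",
      format(object@auc, digits = 4), ", cutoff = ",
      format(object@cutoff, digits = 4), " (", object@direction,
      "), high accuracy = ", object@highAccuracy, "\n", sep = "")
})

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario: ", object@nNodes, "-node interactome, ",
      object@moduleSize, "-protein disease module, ",
      object@nSignal, " signal + ", object@nNull, " null compounds, ",
      object@nGenes, "x", 2L * object@nPerGroup, " expression matrix (seed ",
      object@seed, ")\n", sep = "")
})
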