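# Differential expression, DEG x target intersection, hub targets and
# per-gene diagnostic ROC.

#' Assemble a two-group expression SummarizedExperiment
#'
#' @param values genes x samples numeric matrix of log2-scale expression,
#'   with unique row (gene) and column (sample) names and finite values.
#' @param groups named character/factor mapping each sample to \code{"case"}
#'   or \code{"control"} (names may be omitted if already in column order).
#' @return a \code{SummarizedExperiment} with assay \code{exprs} and colData
#'   column \code{group}.
#' @export
makeExpressionSet <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique gene row names")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("values must have unique sample column names")
  }
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing)) {
      stop("samples without a group: ", paste(utils::head(missing, 5L),
                                              collapse = ", "))
    }
    groups <- groups[colnames(values)]
  } else if (length(groups) != ncol(values)) {
    stop("groups must cover every sample")
  }
  groups <- as.character(groups)
  if (!all(groups %in% c("case", "control"))) {
    stop("groups must be 'case' or 'control'")
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(
      group = factor(groups, levels = c("control", "case")),
      row.names = colnames(values)))
}

#' Expression values of an expression set
#' @param se a \code{SummarizedExperiment} from \code{\link{makeExpressionSet}}.
#' @return the genes x samples matrix.
#' @export
exprValues <- function(se) SummarizedExperiment::assay(se, "exprs")

#' Sample groups of an expression set
#' @param se a \code{SummarizedExperiment} from \code{\link{makeExpressionSet}}.
#' @return factor of \code{control}/\code{case} per sample.
#' @export
sampleGroups <- function(se) SummarizedExperiment::colData(se)$group

#' Call differentially expressed genes
#'
#' Per-gene Welch two-sample t-test on log2 expression (case vs control),
#' Benjamini-Hochberg adjustment across all genes, and the strict
#' |logFC| > \code{lfcThresh} AND adjusted p < \code{alpha} direction rule.
#' logFC is the case minus control mean difference.
#'
#' @param se expression set from \code{\link{makeExpressionSet}}.
#' @param lfcThresh log2 fold-change threshold (default 0.5, strict).
#' @param alpha adjusted-p threshold (default 0.05, strict).
#' @return data.frame: gene, logFC, p_raw, p_adj, direction (up/down/ns),
#'   with attribute \code{orientation = "case_minus_control"}.
#' @export
callDEGs <- function(se, lfcThresh = 0.5, alpha = 0.05) {
  x <- exprValues(se)
  grp <- sampleGroups(se)
  if (sum(grp == "case") < 2L || sum(grp == "control") < 2L) {
    stop("each group needs at least 2 samples")
  }
  case <- x[, grp == "case", drop = FALSE]
  ctrl <- x[, grp == "control", drop = FALSE]
  logFC <- rowMeans(case) - rowMeans(ctrl)
  pRaw <- vapply(seq_len(nrow(x)), function(i) {
    tryCatch(stats::t.test(case[i, ], ctrl[i, ])$p.value,
             error = function(e) {
               # both groups (essentially) constant: p = 1 when the means
               # agree, 0 when they differ (infinite t)
               if (isTRUE(all.equal(logFC[[i]], 0))) 1 else 0
             })
  }, numeric(1L))
  pAdj <- stats::p.adjust(pRaw, method = "BH")
  direction <- rep("ns", nrow(x))
  direction[logFC > lfcThresh & pAdj < alpha] <- "up"
  direction[logFC < -lfcThresh & pAdj < alpha] <- "down"
  out <- data.frame(gene = rownames(x), logFC = unname(logFC),
                    p_raw = pRaw, p_adj = pAdj, direction = direction,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "orientation") <- "case_minus_control"
  out
}

#' Intersect DEGs with compound target sets
#'
#' Keeps only genes called up or down that appear in at least one compound
#' target set; each row lists the compounds containing the gene.
#'
#' @param degs DEG table from \code{\link{callDEGs}}.
#' @param compoundSets list of \linkS4class{TargetSet}s.
#' @return data.frame: gene, direction, compounds (comma-joined),
#'   n_compounds.
#' @export
intersectTargets <- function(degs, compoundSets) {
  sig <- degs[degs$direction %in% c("up", "down"), , drop = FALSE]
  empty <- data.frame(gene = character(0), direction = character(0),
                      compounds = character(0), n_compounds = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0L || length(compoundSets) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    gene <- canonicalizeIds(sig$gene[i])
    hit <- vapply(compoundSets, function(s) gene %in% members(s), logical(1L))
    if (!any(hit)) return(NULL)
    nms <- vapply(compoundSets[hit], setName, character(1L))
    data.frame(gene = gene, direction = sig$direction[i],
               compounds = paste(sort(nms), collapse = ","),
               n_compounds = sum(hit), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Degree-ranked hub targets within a gene subnetwork
#'
#' Degrees are computed in the subgraph induced on \code{genes}; genes are
#' ranked by degree descending with alphabetical tie-break and the top
#' \code{k} are selected.
#'
#' @param subnet an \linkS4class{Interactome} of subnetwork edges (e.g. a
#'   PPI export for the intersection genes).
#' @param genes gene IDs of interest; genes absent from the subnetwork are
#'   dropped with a message.
#' @param k how many hubs to select (default 12).
#' @return data.frame: gene, degree, rank, selected (logical).
#' @export
hubTargets <- function(subnet, genes, k = 12L) {
  stopifnot(methods::is(subnet, "Interactome"))
  if (k <= 0L) stop("k must be positive")
  genes <- .asMembers(genes)
  mapped <- intersect(genes, nodeIds(subnet))
  if (length(mapped) < length(genes)) {
    message("hubTargets: ", length(genes) - length(mapped),
            " gene(s) not in the subnetwork")
  }
  if (length(mapped) == 0L) {
    return(data.frame(gene = character(0), degree = integer(0),
                      rank = integer(0), selected = logical(0)))
  }
  sub <- igraph::induced_subgraph(subnet@graph, mapped)
  deg <- igraph::degree(sub)
  ord <- order(-deg, names(deg))
  out <- data.frame(gene = names(deg)[ord],
                    degree = as.integer(deg[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  out$selected <- out$rank <= k
  rownames(out) <- NULL
  out
}

#' Diagnostic ROC of a single gene's expression
#'
#' Uses the gene's expression values as classifier scores for
#' \code{positiveGroup}. The orientation is chosen so the AUC is at least
#' 0.5 (direction \code{"up"} when high expression marks the positive group,
#' \code{"down"} otherwise); the reported cutoff maximizes Youden's
#' J = sensitivity + specificity - 1 over the observed expression values,
#' with J-ties broken toward higher specificity. A gene with AUC > 0.9 is
#' flagged as a high-accuracy diagnostic biomarker.
#'
#' @param se expression set from \code{\link{makeExpressionSet}}.
#' @param gene gene ID (must be a row of the expression matrix).
#' @param positiveGroup \code{"case"} (default) or \code{"control"}.
#' @return a \linkS4class{DiagnosticResult}. Constant expression yields
#'   AUC 0.5, an undefined cutoff and flag \code{"constant_expression"}.
#' @export
diagnosticROC <- function(se, gene, positiveGroup = "case") {
  x <- exprValues(se)
  gene <- canonicalizeIds(gene)
  if (!gene %in% rownames(x)) stop("gene '", gene, "' not in expression matrix")
  grp <- sampleGroups(se)
  pos <- grp == positiveGroup
  if (sum(pos) == 0L || sum(!pos) == 0L) stop("both groups must be non-empty")
  v <- x[gene, ]
  if (length(unique(v)) == 1L) {
    return(new("DiagnosticResult", gene = gene, auc = 0.5,
               cutoff = NA_real_, sensAtCutoff = NA_real_,
               specAtCutoff = NA_real_, highAccuracy = FALSE,
               direction = "up", flag = "constant_expression"))
  }
  auc0 <- .aucRank(v, pos)
  direction <- if (auc0 >= 0.5) "up" else "down"
  s <- if (direction == "up") v else -v
  auc <- .aucRank(s, pos)
  ths <- sort(unique(s))
  sens <- vapply(ths, function(t) mean(s[pos] >= t), numeric(1L))
  spec <- vapply(ths, function(t) mean(s[!pos] < t), numeric(1L))
  J <- sens + spec - 1
  best <- order(-J, -spec, ths)[1L]
  cutoff <- if (direction == "up") ths[best] else -ths[best]
  new("DiagnosticResult", gene = gene, auc = auc, cutoff = cutoff,
      sensAtCutoff = sens[best], specAtCutoff = spec[best],
      highAccuracy = auc > 0.9, direction = direction, flag = "ok")
}

#' Tabulate diagnostic results
#'
#' @param results list of \linkS4class{DiagnosticResult}s.
#' @return data.frame: gene, auc, cutoff, sensitivity, specificity,
#'   direction, high_accuracy, flag.
#' @export
diagnosticTable <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(gene = r@gene, auc = r@auc, cutoff = r@cutoff,
               sensitivity = r@sensAtCutoff, specificity = r@specAtCutoff,
               direction = r@direction, high_accuracy = r@highAccuracy,
               flag = r@flag, stringsAsFactors = FALSE)
  }))
}
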