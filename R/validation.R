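# ROC validation: does network proximity separate known therapeutic
# compound-disease pairs from unconnected ones?

#' Proximity scores for compound--disease pairs
#'
#' For each requested pair the closest-metric proximity z-score is computed
#' (compound targets randomized, disease set fixed) and returned as
#' score = -z_closest, so that higher scores mean more likely therapeutic.
#'
#' @param g the analysis \linkS4class{Interactome}.
#' @param compoundSets named list of \linkS4class{TargetSet}s.
#' @param diseaseSets named list of \linkS4class{TargetSet}s.
#' @param pairs data.frame with columns \code{compound}, \code{disease} and
#'   optionally \code{label}; defaults to the full cross product.
#' @param bins \linkS4class{DegreeBins} on \code{g}.
#' @param nReps null replicates per pair (default 1000).
#' @param seed optional seed (each pair derives its own stream).
#' @return data.frame: compound, disease, z_closest, score and, when given,
#'   label. Pairs whose sets cannot be mapped into the graph are excluded
#'   with a warning.
#' @export
scorePairs <- function(g, compoundSets, diseaseSets, pairs = NULL, bins,
                       nReps = 1000L, seed = NULL) {
  if (is.null(pairs)) {
    pairs <- expand.grid(compound = names(compoundSets),
                         disease = names(diseaseSets),
                         stringsAsFactors = FALSE)
  }
  if (anyDuplicated(pairs[, c("compound", "disease")])) {
    stop("duplicate (compound, disease) pairs")
  }
  rows <- vector("list", nrow(pairs))
  dropped <- 0L
  for (dz in unique(pairs$disease)) {
    sel <- which(pairs$disease == dz)
    for (i in sel) {
      cm <- pairs$compound[i]
      res <- tryCatch(
        proximityZScore(g, compoundSets[[cm]], diseaseSets[[dz]], bins,
                        metric = "closest", nReps = nReps,
                        seed = repSeed(seed, i), compound = cm),
        error = function(e) NULL)
      if (is.null(res)) {
        dropped <- dropped + 1L
        next
      }
      rows[[i]] <- data.frame(compound = cm, disease = dz,
                              z_closest = res@zClosest,
                              score = -res@zClosest,
                              stringsAsFactors = FALSE)
      if ("label" %in% names(pairs)) rows[[i]]$label <- pairs$label[i]
    }
  }
  if (dropped > 0L) warning(dropped, " unmappable pair(s) excluded")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out) || nrow(out) == 0L) stop("no scorable pairs")
  rownames(out) <- NULL
  out
}

# Internal: AUC by pair counting (Mann-Whitney; ties count 0.5), via ranks.
.aucRank <- function(scores, labels) {
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  (sum(rank(scores)[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' ROC curve and AUC
#'
#' The AUC equals the Mann-Whitney pair statistic of the scores (concordant
#' pairs count 1, ties 0.5). The curve is a threshold sweep over the unique
#' scores with a ">= threshold is positive" rule.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical (TRUE = positive) or a factor/character vector with
#'   \code{"therapeutic"} marking positives.
#' @return an \linkS4class{ROCResult}.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3), c(TRUE, FALSE, TRUE))  # AUC 0.5
#' @export
rocAuc <- function(scores, labels) {
  if (!is.logical(labels)) labels <- as.character(labels) == "therapeutic"
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L) stop("need at least one positive and one negative")
  auc <- .aucRank(scores, labels)
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(ths, function(t) sum(scores[labels] >= t) / nPos, numeric(1L))
  fpr <- vapply(ths, function(t) sum(scores[!labels] >= t) / nNeg, numeric(1L))
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1) {
    curve <- rbind(curve, data.frame(fpr = 1, tpr = 1))
  }
  new("ROCResult", auc = auc, nPos = nPos, nNeg = nNeg, curve = curve,
      compareP = NA_real_)
}

#' Compare two AUCs by stratified bootstrap
#'
#' Positives and negatives of each score set are resampled independently
#' \code{nBoot} times; the two-sided p-value is the (smoothed) percentile
#' probability that the bootstrap AUC difference crosses zero.
#'
#' @param scoresA,labelsA first score/label set.
#' @param scoresB,labelsB second score/label set.
#' @param nBoot bootstrap replicates (default 2000).
#' @param seed optional seed.
#' @return list with \code{aucA}, \code{aucB}, \code{diff} and \code{p}.
#' @export
compareAuc <- function(scoresA, labelsA, scoresB, labelsB, nBoot = 2000L,
                       seed = NULL) {
  if (!is.logical(labelsA)) labelsA <- as.character(labelsA) == "therapeutic"
  if (!is.logical(labelsB)) labelsB <- as.character(labelsB) == "therapeutic"
  aucA <- rocAuc(scoresA, labelsA)@auc
  aucB <- rocAuc(scoresB, labelsB)@auc
  posA <- scoresA[labelsA]; negA <- scoresA[!labelsA]
  posB <- scoresB[labelsB]; negB <- scoresB[!labelsB]
  diffs <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      sa <- c(.sampleBoot(posA), .sampleBoot(negA))
      la <- c(rep(TRUE, length(posA)), rep(FALSE, length(negA)))
      sb <- c(.sampleBoot(posB), .sampleBoot(negB))
      lb <- c(rep(TRUE, length(posB)), rep(FALSE, length(negB)))
      .aucRank(sa, la) - .aucRank(sb, lb)
    }, numeric(1L))
  })
  pLo <- (1 + sum(diffs <= 0)) / (nBoot + 1)
  pHi <- (1 + sum(diffs >= 0)) / (nBoot + 1)
  p <- min(1, 2 * min(pLo, pHi))
  list(aucA = aucA, aucB = aucB, diff = aucA - aucB, p = p)
}

.sampleBoot <- function(x) x[sample.int(length(x), length(x), replace = TRUE)]

#' Write an ROC result (curve TSV + JSON summary)
#'
#' @param roc an \linkS4class{ROCResult}.
#' @param tsvPath path for the (fpr, tpr) curve TSV.
#' @param jsonPath optional JSON summary path.
#' @param extra optional named list merged into the JSON summary.
#' @return invisibly, \code{tsvPath}.
#' @export
writeROC <- function(roc, tsvPath, jsonPath = NULL, extra = list()) {
  utils::write.table(roc@curve, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(jsonPath)) {
    .writeJSON(c(list(auc = roc@auc, nPos = roc@nPos, nNeg = roc@nNeg,
                      compareP = roc@compareP), extra), jsonPath)
  }
  invisible(tsvPath)
}
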