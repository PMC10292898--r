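# Batch orchestration: run the whole screen from plain-text inputs to
# per-stage TSV/JSON outputs plus a run manifest.

#' Assemble and validate a pipeline run configuration
#'
#' @param edgeFile interactome edge-list TSV (\code{protein_a},
#'   \code{protein_b}, optional \code{source}).
#' @param targetsFile compound target sets (GMT or set_name/member TSV).
#' @param diseaseFile disease protein set (one ID per line).
#' @param associationFile optional compound-disease association TSV.
#' @param diseaseSetsFile optional GMT of disease protein sets for the
#'   association pairs.
#' @param exprFile,sampleSheet optional expression TSV + sample sheet.
#' @param subnetFile optional edge-list TSV for the hub subnetwork; the
#'   interactome itself is used when absent.
#' @param nReps null replicates for every z-score (default 1000).
#' @param minBinSize degree-bin occupancy (default 100).
#' @param zThreshold LCC screening threshold on |z| (default 1.70).
#' @param lfcThresh,alpha DEG thresholds (defaults 0.5, 0.05).
#' @param kTopCompounds compounds kept by the proximity screen (default 8).
#' @param kHubs hub targets selected (default 12).
#' @param lccScope \code{"disease"} (compound LCCs inside the
#'   disease-protein-induced subgraph) or \code{"full"} (whole analysis
#'   component).
#' @param seed master seed; recorded in every output artifact.
#' @param outputDir directory for stage outputs (created if needed).
#' @param skipStages character vector of stage names to skip.
#' @return a validated configuration (class \code{RunConfig}).
#' @export
runConfig <- function(edgeFile, targetsFile, diseaseFile,
                      associationFile = NULL, diseaseSetsFile = NULL,
                      exprFile = NULL, sampleSheet = NULL, subnetFile = NULL,
                      nReps = 1000L, minBinSize = 100L, zThreshold = 1.70,
                      lfcThresh = 0.5, alpha = 0.05, kTopCompounds = 8L,
                      kHubs = 12L, lccScope = c("disease", "full"),
                      seed = 1L, outputDir, skipStages = character(0)) {
  lccScope <- match.arg(lccScope)
  stopifnot(nReps > 0L, minBinSize > 0L, zThreshold > 0, lfcThresh > 0,
            alpha > 0, kTopCompounds > 0L, kHubs > 0L)
  for (f in c(edgeFile, targetsFile, diseaseFile, associationFile,
              diseaseSetsFile, exprFile, sampleSheet, subnetFile)) {
    if (!is.null(f) && !file.exists(f)) stop("input not readable: ", f)
  }
  cfg <- list(edgeFile = edgeFile, targetsFile = targetsFile,
              diseaseFile = diseaseFile, associationFile = associationFile,
              diseaseSetsFile = diseaseSetsFile, exprFile = exprFile,
              sampleSheet = sampleSheet, subnetFile = subnetFile,
              nReps = as.integer(nReps), minBinSize = as.integer(minBinSize),
              zThreshold = zThreshold, lfcThresh = lfcThresh, alpha = alpha,
              kTopCompounds = as.integer(kTopCompounds),
              kHubs = as.integer(kHubs), lccScope = lccScope,
              seed = as.integer(seed), outputDir = outputDir,
              skipStages = skipStages)
  class(cfg) <- "RunConfig"
  cfg
}

.pipelineStages <- c("build", "ji", "lcc", "prox", "screen", "validate",
                     "deg", "intersect", "hubs", "diag")

#' Run the full screening pipeline
#'
#' Stages, in order: \code{build} (interactome + analysis component),
#' \code{ji} (pairwise Jaccard), \code{lcc} (per-compound LCC z screen),
#' \code{prox} (proximity z per compound vs the disease set), \code{screen}
#' (top-k ranking), \code{validate} (association ROC), \code{deg}
#' (differential expression), \code{intersect} (DEG x target intersection),
#' \code{hubs} (degree-ranked hub targets) and \code{diag} (per-hub
#' diagnostic ROC). Stages may be skipped via the configuration; a stage
#' whose inputs are missing (or whose upstream stage was skipped) is marked
#' skipped in the manifest. A stage failure aborts the run with the failing
#' stage named; outputs of completed stages are retained.
#'
#' @param config a configuration from \code{\link{runConfig}}.
#' @return the run manifest (list), also written to
#'   \code{outputDir/manifest.json}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outputDir, ...)
  manifest <- list(package = "netRepurpose",
                   version = as.character(utils::packageVersion("netRepurpose")),
                   seed = config$seed, lccScope = config$lccScope,
                   nReps = config$nReps, stages = list())
  state <- new.env(parent = emptyenv())
  done <- character(0)

  runStage <- function(name, needs = character(0), inputsOk = TRUE, fun) {
    status <- NULL
    t0 <- proc.time()[["elapsed"]]
    if (name %in% config$skipStages) {
      status <- list(status = "skipped", reason = "disabled in config")
    } else if (!all(needs %in% done)) {
      status <- list(status = "skipped",
                     reason = paste("missing upstream stage:",
                                    paste(setdiff(needs, done), collapse = ",")))
    } else if (!inputsOk) {
      status <- list(status = "skipped", reason = "inputs not provided")
    } else {
      counts <- tryCatch(fun(),
                         error = function(e) {
                           stop("pipeline stage '", name, "' failed: ",
                                conditionMessage(e), call. = FALSE)
                         })
      done <<- c(done, name)
      status <- list(status = "complete",
                     seconds = round(proc.time()[["elapsed"]] - t0, 3))
      if (length(counts)) status$counts <- counts
    }
    manifest$stages[[name]] <<- status
    invisible(NULL)
  }

  runStage("build", fun = function() {
    raw <- readEdgeList(config$edgeFile)
    state$interactome <- analysisComponent(raw)
    state$compoundSets <- readTargetSets(config$targetsFile)
    state$disease <- readNodeSet(config$diseaseFile, name = "DISEASE")
    writeLoadReport(raw, out("load_report.json"))
    state$bins <- makeDegreeBins(state$interactome, config$minBinSize)
    .writeJSON(binSummary(state$bins), out("degree_bins.json"))
    list(nodes = nodeCount(state$interactome),
         edges = edgeCount(state$interactome),
         compounds = length(state$compoundSets),
         diseaseProteins = length(members(state$disease)))
  })

  runStage("ji", needs = "build", fun = function() {
    sm <- pairwiseJaccard(state$compoundSets)
    writeSimilarity(sm, out("jaccard.tsv"), out("jaccard.json"))
    list(meanOffdiag = meanOffdiag(sm))
  })

  runStage("lcc", needs = "build", fun = function() {
    if (config$lccScope == "disease") {
      gLCC <- diseaseSubgraph(state$interactome, state$disease)
    } else {
      gLCC <- state$interactome
    }
    binsLCC <- if (config$lccScope == "disease") {
      suppressWarnings(makeDegreeBins(gLCC, min(config$minBinSize,
                                                max(1L, nodeCount(gLCC)))))
    } else {
      state$bins
    }
    res <- lapply(names(state$compoundSets), function(cm) {
      lccZScore(gLCC, state$compoundSets[[cm]], binsLCC,
                nReps = config$nReps, zThreshold = config$zThreshold,
                seed = repSeed(config$seed, match(cm, names(state$compoundSets))))
    })
    state$lcc <- res
    tab <- lccTable(res)
    utils::write.table(tab, out("lcc.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(evaluated = sum(tab$flag != "not_evaluated"),
         significant = sum(tab$significant))
  })

  runStage("prox", needs = "build", fun = function() {
    res <- lapply(names(state$compoundSets), function(cm) {
      networkProximity(state$interactome, state$compoundSets[[cm]],
                       state$disease, state$bins, nReps = config$nReps,
                       seed = repSeed(config$seed,
                                      1000L + match(cm, names(state$compoundSets))))
    })
    state$prox <- res
    utils::write.table(proximityTable(res), out("proximity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(compounds = length(res))
  })

  runStage("screen", needs = "prox", fun = function() {
    top <- rankCompounds(state$prox, k = min(config$kTopCompounds,
                                             length(state$prox)))
    state$top <- top
    utils::write.table(proximityTable(top), out("top_compounds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(k = length(top))
  })

  runStage("validate", needs = c("build", "screen"),
           inputsOk = !is.null(config$associationFile) &&
             !is.null(config$diseaseSetsFile), fun = function() {
    pairs <- readAssociations(config$associationFile)
    diseaseSets <- readTargetSets(config$diseaseSetsFile)
    scored <- scorePairs(state$interactome, state$compoundSets, diseaseSets,
                         pairs = pairs, bins = state$bins,
                         nReps = config$nReps,
                         seed = repSeed(config$seed, 2000L))
    state$scored <- scored
    roc <- rocAuc(scored$score, scored$label)
    state$validationROC <- roc
    utils::write.table(scored, out("pair_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeROC(roc, out("validation_roc.tsv"), out("validation_roc.json"),
             extra = list(seed = config$seed))
    list(auc = roc@auc, nPos = roc@nPos, nNeg = roc@nNeg)
  })

  runStage("deg", needs = character(0),
           inputsOk = !is.null(config$exprFile) &&
             !is.null(config$sampleSheet), fun = function() {
    state$se <- readExpressionTSV(config$exprFile, config$sampleSheet)
    degs <- callDEGs(state$se, lfcThresh = config$lfcThresh,
                     alpha = config$alpha)
    state$degs <- degs
    utils::write.table(degs, out("degs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(genes = nrow(degs), up = sum(degs$direction == "up"),
         down = sum(degs$direction == "down"))
  })

  runStage("intersect", needs = c("deg", "screen"), fun = function() {
    topSets <- state$compoundSets[vapply(state$top, function(r) r@compound,
                                         character(1L))]
    inter <- intersectTargets(state$degs, topSets)
    state$intersection <- inter
    utils::write.table(inter, out("intersection.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(genes = nrow(inter), up = sum(inter$direction == "up"),
         down = sum(inter$direction == "down"))
  })

  runStage("hubs", needs = "intersect", fun = function() {
    subnet <- if (!is.null(config$subnetFile)) {
      readEdgeList(config$subnetFile)
    } else {
      state$interactome
    }
    hubs <- hubTargets(subnet, state$intersection$gene, k = config$kHubs)
    state$hubs <- hubs
    utils::write.table(hubs, out("hub_targets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(candidates = nrow(hubs), selected = sum(hubs$selected))
  })

  runStage("diag", needs = c("hubs", "deg"), fun = function() {
    sel <- state$hubs$gene[state$hubs$selected]
    sel <- intersect(sel, rownames(exprValues(state$se)))
    res <- lapply(sel, function(gn) diagnosticROC(state$se, gn))
    tab <- diagnosticTable(res)
    state$diag <- tab
    utils::write.table(tab, out("diagnostic_roc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .writeJSON(tab, out("diagnostic_roc.json"))
    list(genes = if (is.null(tab)) 0L else nrow(tab),
         highAccuracy = if (is.null(tab)) 0L else sum(tab$high_accuracy))
  })

  manifest$completed <- done
  .writeJSON(manifest, out("manifest.json"))
  invisible(manifest)
}
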