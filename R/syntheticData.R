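# Synthetic study generator: a scale-free interactome with a planted,
# connected disease module, compounds whose targets either overlap the module
# neighborhood (signal) or are degree-matched random (null), a two-group
# expression matrix with planted differential expression, and a
# compound-disease association benchmark. Every stage derives its own RNG
# stream from the scenario's master seed (base R Mersenne-Twister), so the
# whole bundle is reproducible from one integer.

# Fixed offsets for the per-stage derived seeds.
.stageSeed <- function(scenario, stage) {
  off <- c(graph = 1L, module = 2L, compounds = 3L, expression = 4L,
           associations = 5L)
  repSeed(scenario@seed, off[[stage]])
}

#' Generate a scale-free interactome
#'
#' Preferential-attachment growth (each new node attaches to
#' \code{attachment} existing nodes), which guarantees a single connected
#' component and a heavy-tailed degree distribution.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @return an \linkS4class{Interactome} with \code{nNodes} nodes.
#' @examples
#' g <- generateInteractome(syntheticScenario(seed = 1, nNodes = 100))
#' @export
generateInteractome <- function(scenario) {
  stopifnot(methods::is(scenario, "SyntheticScenario"))
  g <- withSeed(.stageSeed(scenario, "graph"), {
    igraph::sample_pa(scenario@nNodes, power = 1, m = scenario@attachment,
                      directed = FALSE)
  })
  igraph::V(g)$name <- sprintf("P%05d", seq_len(scenario@nNodes))
  el <- igraph::as_edgelist(g)
  buildInteractome(data.frame(protein_a = el[, 1L], protein_b = el[, 2L],
                              stringsAsFactors = FALSE))
}

#' Plant a connected disease module
#'
#' Grows a connected node set of \code{moduleSize} by breadth-first search
#' from a random root.
#'
#' @param g the synthetic \linkS4class{Interactome}.
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @return a \linkS4class{TargetSet} named \code{"DISEASE_MODULE"}.
#' @export
plantDiseaseModule <- function(g, scenario) {
  stopifnot(methods::is(g, "Interactome"),
            methods::is(scenario, "SyntheticScenario"))
  mem <- withSeed(.stageSeed(scenario, "module"), {
    root <- .sampleVec(nodeIds(g), 1L)
    ord <- igraph::bfs(g@graph, root = root, unreachable = FALSE)$order
    igraph::V(g@graph)$name[as.integer(ord)[seq_len(scenario@moduleSize)]]
  })
  stopifnot(!anyNA(mem))
  mod <- TargetSet("DISEASE_MODULE", mem)
  # BFS order grows a connected set by construction; assert anyway
  stopifnot(igraph::is_connected(igraph::induced_subgraph(g@graph, mem)))
  mod
}

# Internal: the module and its first neighbors -- the "signal" pool.
.moduleNeighborhood <- function(g, module) {
  mem <- .asMembers(module)
  nbr <- igraph::V(g@graph)$name[unlist(igraph::adjacent_vertices(
    g@graph, mem), use.names = FALSE)]
  union(mem, unique(nbr))
}

#' Plant signal and null compounds
#'
#' Signal compounds draw \code{round(overlapFraction * targetsPerCompound)}
#' targets from the disease module and its first neighbors -- stratified, half
#' from inside the module and half from the adjacent shell, so the planted
#' compounds genuinely perturb the module rather than merely orbiting it --
#' and the remainder uniformly from the rest of the graph. Null compounds are
#' degree-matched resamples of a signal compound's target profile
#' (bin-by-bin, like the analysis null), so the screen separates location,
#' not degree.
#'
#' @param g the synthetic \linkS4class{Interactome}.
#' @param module the planted disease module (\linkS4class{TargetSet}).
#' @param bins \linkS4class{DegreeBins} on \code{g}.
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @return list with \code{sets} (named list of \linkS4class{TargetSet}s)
#'   and \code{truth} (data.frame: compound, is_signal).
#' @export
plantCompounds <- function(g, module, bins, scenario) {
  stopifnot(methods::is(scenario, "SyntheticScenario"))
  inside <- .asMembers(module)
  shell <- setdiff(.moduleNeighborhood(g, module), inside)
  tpc <- scenario@targetsPerCompound
  nOverlap <- round(scenario@overlapFraction * tpc)
  outPool <- setdiff(nodeIds(g), union(inside, shell))
  withSeed(.stageSeed(scenario, "compounds"), {
    signal <- lapply(seq_len(scenario@nSignal), function(i) {
      kIn <- min(ceiling(nOverlap / 2), length(inside))
      kAdj <- min(nOverlap - kIn, length(shell))
      kIn <- min(nOverlap - kAdj, length(inside))
      TargetSet(sprintf("CMPD_SIG_%02d", i),
                c(.sampleVec(inside, kIn), .sampleVec(shell, kAdj),
                  .sampleVec(outPool, tpc - kIn - kAdj)))
    })
    nulls <- lapply(seq_len(scenario@nNull), function(j) {
      template <- signal[[(j - 1L) %% scenario@nSignal + 1L]]
      TargetSet(sprintf("CMPD_NULL_%02d", j),
                sampleDegreeMatched(template, bins))
    })
    sets <- c(signal, nulls)
    names(sets) <- vapply(sets, setName, character(1L))
    truth <- data.frame(compound = names(sets),
                        is_signal = c(rep(TRUE, scenario@nSignal),
                                      rep(FALSE, scenario@nNull)),
                        stringsAsFactors = FALSE)
    list(sets = sets, truth = truth)
  })
}

#' Generate a two-group expression matrix with planted DE genes
#'
#' Baseline per-gene means are uniform on [6, 12] (log2 intensity scale);
#' case samples of planted genes are shifted by \code{±effectLogFC} (random
#' sign), and i.i.d. Gaussian noise with sd \code{noiseSd} is added
#' everywhere.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param geneIds gene universe (length \code{nGenes}); defaults to
#'   synthetic IDs.
#' @param deGeneIds genes to plant as differentially expressed; defaults to
#'   a random \code{deFraction} of the universe.
#' @return list with \code{se} (a \code{SummarizedExperiment}) and
#'   \code{truth} (data.frame: gene, is_de, direction).
#' @export
generateExpression <- function(scenario, geneIds = NULL, deGeneIds = NULL) {
  stopifnot(methods::is(scenario, "SyntheticScenario"))
  nG <- scenario@nGenes
  if (is.null(geneIds)) geneIds <- sprintf("G%05d", seq_len(nG))
  geneIds <- unique(canonicalizeIds(geneIds))
  stopifnot(length(geneIds) == nG)
  nS <- scenario@nPerGroup
  withSeed(.stageSeed(scenario, "expression"), {
    if (is.null(deGeneIds)) {
      deGeneIds <- .sampleVec(geneIds, round(scenario@deFraction * nG))
    } else {
      deGeneIds <- intersect(canonicalizeIds(deGeneIds), geneIds)
    }
    isDE <- geneIds %in% deGeneIds
    sign <- rep(0, nG)
    sign[isDE] <- ifelse(stats::runif(sum(isDE)) < 0.5, 1, -1)
    base <- stats::runif(nG, 6, 12)
    samples <- c(sprintf("CTRL_%02d", seq_len(nS)),
                 sprintf("CASE_%02d", seq_len(nS)))
    mu <- cbind(matrix(rep(base, nS), ncol = nS),
                matrix(rep(base + sign * scenario@effectLogFC, nS), ncol = nS))
    vals <- mu + matrix(stats::rnorm(nG * 2L * nS, sd = scenario@noiseSd),
                        nrow = nG)
    dimnames(vals) <- list(geneIds, samples)
    groups <- stats::setNames(rep(c("control", "case"), each = nS), samples)
    truth <- data.frame(gene = geneIds, is_de = isDE,
                        direction = c("ns", "up", "down")[
                          1L + (sign > 0) + 2L * (sign < 0)],
                        stringsAsFactors = FALSE)
    list(se = makeExpressionSet(vals, groups), truth = truth)
  })
}

#' Generate a compound--disease association benchmark
#'
#' For each given compound, therapeutic diseases get protein sets drawn from
#' the compound's target neighborhood (targets plus first neighbors), and
#' non-therapeutic diseases get degree-matched random resamples of such a
#' set, emulating validation against known indications plus unconnected
#' negatives.
#'
#' @param g the synthetic \linkS4class{Interactome}.
#' @param bins \linkS4class{DegreeBins} on \code{g}.
#' @param compoundSets named list of \linkS4class{TargetSet}s to pair.
#' @param nPerCompound diseases generated per compound (default 20).
#' @param fracTherapeutic fraction labeled therapeutic (default 0.5).
#' @param diseaseSetSize proteins per disease set (default 15).
#' @param seed seed for this stage.
#' @return list with \code{pairs} (data.frame: compound, disease, label)
#'   and \code{diseaseSets} (named list of \linkS4class{TargetSet}s).
#' @export
generateAssociations <- function(g, bins, compoundSets, nPerCompound = 20L,
                                 fracTherapeutic = 0.5, diseaseSetSize = 15L,
                                 seed = NULL) {
  stopifnot(methods::is(g, "Interactome"))
  withSeed(seed, {
    pairs <- list()
    diseaseSets <- list()
    for (cm in names(compoundSets)) {
      hood <- .moduleNeighborhood(g, compoundSets[[cm]])
      nTher <- round(fracTherapeutic * nPerCompound)
      for (k in seq_len(nPerCompound)) {
        ther <- k <= nTher
        nm <- sprintf("DIS_%s_%02d", cm, k)
        base <- .sampleVec(hood, min(diseaseSetSize, length(hood)))
        memb <- if (ther) base else sampleDegreeMatched(base, bins)
        diseaseSets[[nm]] <- TargetSet(nm, memb)
        pairs[[length(pairs) + 1L]] <- data.frame(
          compound = cm, disease = nm,
          label = if (ther) "therapeutic" else "non_therapeutic",
          stringsAsFactors = FALSE)
      }
    }
    list(pairs = do.call(rbind, pairs), diseaseSets = diseaseSets)
  })
}

#' Generate the full synthetic study
#'
#' Runs every generator stage under the scenario's master seed and returns
#' all objects plus the ground truth needed to score any downstream stage.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param minBinSize degree-bin occupancy for the bundled
#'   \linkS4class{DegreeBins} (default 100).
#' @param nDiseasesPerCompound,fracTherapeutic,diseaseSetSize passed to
#'   \code{\link{generateAssociations}} (applied to the signal compounds).
#' @return list: interactome, bins, module, compounds (sets + truth),
#'   expression (se + truth), associations (pairs + diseaseSets), scenario.
#' @export
simulateStudy <- function(scenario, minBinSize = 100L,
                          nDiseasesPerCompound = 20L, fracTherapeutic = 0.5,
                          diseaseSetSize = 15L) {
  g <- generateInteractome(scenario)
  bins <- makeDegreeBins(g, minBinSize = minBinSize)
  module <- plantDiseaseModule(g, scenario)
  compounds <- plantCompounds(g, module, bins, scenario)
  # gene universe: compound targets and module proteins first, padded with
  # other interactome nodes, so expression truth aligns with the network
  allTargets <- unique(c(unlist(lapply(compounds$sets, members),
                                use.names = FALSE), members(module)))
  padPool <- setdiff(nodeIds(g), allTargets)
  nPad <- scenario@nGenes - length(allTargets)
  if (nPad < 0L) stop("nGenes too small for the compound target universe")
  geneIds <- withSeed(repSeed(scenario@seed, 6L), {
    c(allTargets, .sampleVec(padPool, min(nPad, length(padPool))))
  })
  if (length(geneIds) < scenario@nGenes) {
    geneIds <- c(geneIds, sprintf("G%05d", seq_len(scenario@nGenes -
                                                     length(geneIds))))
  }
  expression <- generateExpression(scenario, geneIds = geneIds)
  signalSets <- compounds$sets[compounds$truth$is_signal]
  associations <- generateAssociations(
    g, bins, signalSets, nPerCompound = nDiseasesPerCompound,
    fracTherapeutic = fracTherapeutic, diseaseSetSize = diseaseSetSize,
    seed = .stageSeed(scenario, "associations"))
  list(interactome = g, bins = bins, module = module, compounds = compounds,
       expression = expression, associations = associations,
       scenario = scenario)
}

#' Write a complete synthetic input bundle to a directory
#'
#' Produces the plain-text inputs the pipeline consumes: \code{edges.tsv},
#' \code{compound_targets.gmt}, \code{disease_proteins.txt},
#' \code{associations.tsv}, \code{disease_sets.gmt}, \code{expression.tsv},
#' \code{samples.tsv} and \code{truth.json}.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param dir output directory (created if needed).
#' @param ... passed to \code{\link{simulateStudy}}.
#' @return invisibly, the study list from \code{\link{simulateStudy}}.
#' @export
writeSyntheticBundle <- function(scenario, dir, ...) {
  study <- simulateStudy(scenario, ...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeEdgeList(study$interactome, file.path(dir, "edges.tsv"))
  writeGMT(study$compounds$sets, file.path(dir, "compound_targets.gmt"))
  writeLines(members(study$module), file.path(dir, "disease_proteins.txt"))
  utils::write.table(study$associations$pairs,
                     file.path(dir, "associations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeGMT(study$associations$diseaseSets, file.path(dir, "disease_sets.gmt"))
  x <- exprValues(study$expression$se)
  utils::write.table(data.frame(gene = rownames(x), x, check.names = FALSE),
                     file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(x),
                                group = as.character(sampleGroups(
                                  study$expression$se))),
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .writeJSON(list(seed = study$scenario@seed,
                  module = members(study$module),
                  compound_truth = study$compounds$truth,
                  de_truth = study$expression$truth[
                    study$expression$truth$is_de, ]),
             file.path(dir, "truth.json"))
  invisible(study)
}
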