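# Degree-binned random node sampling: the shared null model behind the LCC
# and proximity z-scores. A scale-free interactome has few very-high-degree
# hubs; matching replicates degree-for-degree (uniform sampling within degree
# bins) stops those hubs from dominating every random replicate.

#' Partition interactome nodes into degree bins
#'
#' Bins are grown greedily from the lowest degree upward: consecutive degree
#' values are accumulated until the bin holds at least \code{minBinSize}
#' nodes, then the bin is closed. A final undersized remainder is merged into
#' the previous bin, so every bin of a multi-bin partition meets the minimum.
#'
#' @param g an \linkS4class{Interactome}.
#' @param minBinSize minimum nodes per bin (default 100, a common choice for
#'   genome-scale interactomes; small graphs collapse to fewer bins).
#' @return a \linkS4class{DegreeBins}.
#' @examples
#' g <- generateInteractome(syntheticScenario(seed = 1, nNodes = 300))
#' bins <- makeDegreeBins(g, minBinSize = 25)
#' @export
makeDegreeBins <- function(g, minBinSize = 100L) {
  stopifnot(methods::is(g, "Interactome"))
  minBinSize <- as.integer(minBinSize)
  if (minBinSize < 1L) stop("minBinSize must be >= 1")
  deg <- nodeDegrees(g)
  if (length(deg) == 0L) stop("empty interactome")
  if (minBinSize > length(deg)) {
    warning("minBinSize exceeds node count; using a single bin")
  }
  byDeg <- split(names(deg), deg)
  degVals <- as.integer(names(byDeg))
  ord <- order(degVals)
  byDeg <- byDeg[ord]
  degVals <- degVals[ord]

  bins <- list()
  ranges <- list()
  cur <- character(0)
  lo <- degVals[1L]
  for (k in seq_along(degVals)) {
    cur <- c(cur, byDeg[[k]])
    if (length(cur) >= minBinSize || k == length(degVals)) {
      bins[[length(bins) + 1L]] <- cur
      ranges[[length(ranges) + 1L]] <- c(lo, degVals[k])
      cur <- character(0)
      if (k < length(degVals)) lo <- degVals[k + 1L]
    }
  }
  # merge an undersized trailing remainder into the previous bin
  n <- length(bins)
  if (n > 1L && length(bins[[n]]) < minBinSize) {
    bins[[n - 1L]] <- c(bins[[n - 1L]], bins[[n]])
    ranges[[n - 1L]] <- c(ranges[[n - 1L]][1L], ranges[[n]][2L])
    bins <- bins[-n]
    ranges <- ranges[-n]
  }

  idx <- rep.int(seq_along(bins), lengths(bins))
  names(idx) <- unlist(bins, use.names = FALSE)
  rangeDf <- data.frame(lower = vapply(ranges, `[`, numeric(1L), 1L),
                        upper = vapply(ranges, `[`, numeric(1L), 2L),
                        size = lengths(bins))
  new("DegreeBins", binMembers = bins, binIndex = idx, binRanges = rangeDf,
      minBinSize = minBinSize)
}

#' Draw a degree-matched random node set
#'
#' Returns a random set of the same size as \code{target} containing, for
#' every degree bin, exactly as many nodes as the target does -- sampled
#' uniformly without replacement within the bin.
#'
#' @param target node IDs (or a \linkS4class{TargetSet}); all must be binned.
#' @param bins a \linkS4class{DegreeBins} built on the analysis graph.
#' @param seed optional integer seed; the draw is deterministic given it.
#' @return character vector of sampled node IDs.
#' @export
sampleDegreeMatched <- function(target, bins, seed = NULL) {
  stopifnot(methods::is(bins, "DegreeBins"))
  target <- .asMembers(target)
  idx <- bins@binIndex[target]
  if (anyNA(idx)) {
    stop("target nodes not covered by the degree bins: ",
         paste(utils::head(target[is.na(idx)], 5L), collapse = ", "))
  }
  counts <- tabulate(idx, nbins = length(bins@binMembers))
  out <- withSeed(seed, {
    unlist(lapply(seq_along(counts), function(b) {
      k <- counts[b]
      if (k == 0L) return(character(0))
      pool <- bins@binMembers[[b]]
      if (k > length(pool)) {
        stop("bin ", b, " cannot supply ", k, " nodes")
      }
      .sampleVec(pool, k)
    }), use.names = FALSE)
  })
  # bin-count preservation, asserted on every draw
  stopifnot(identical(tabulate(bins@binIndex[out],
                               nbins = length(bins@binMembers)), counts))
  out
}

# Internal: precomputed degree-matched sampler for hot replicate loops.
# Resolves the target's bin occupancy once; each call draws one replicate
# with exactly the target's per-bin counts (preserved by construction).
.binSampler <- function(target, bins) {
  idx <- bins@binIndex[target]
  if (anyNA(idx)) {
    stop("target nodes not covered by the degree bins: ",
         paste(utils::head(target[is.na(idx)], 5L), collapse = ", "))
  }
  counts <- tabulate(idx, nbins = length(bins@binMembers))
  active <- which(counts > 0L)
  pools <- bins@binMembers[active]
  ks <- counts[active]
  poolSizes <- lengths(pools)
  if (any(ks > poolSizes)) stop("a bin cannot supply enough nodes")
  function() {
    unlist(lapply(seq_along(active), function(b) {
      pools[[b]][sample.int(poolSizes[b], ks[b])]
    }), use.names = FALSE)
  }
}

# Internal: null replicate values of a statistic over degree-matched samples.
# statFun takes a character vector of node IDs and returns a scalar.
# Replicate r runs under its own derived seed, so results are independent of
# evaluation order; the caller's RNG state is restored afterwards.
.nullReplicates <- function(target, bins, nReps, seed, statFun) {
  sampler <- .binSampler(target, bins)
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  vapply(seq_len(nReps), function(r) {
    if (!is.null(seed)) set.seed(repSeed(seed, r))
    statFun(sampler())
  }, numeric(1L))
}

# Internal: z-score against a null distribution, with the degenerate-sigma
# convention shared by the LCC and proximity analyses.
.zAgainstNull <- function(obs, null) {
  if (null@sigma > 0) {
    list(z = (obs - null@mu) / null@sigma, flag = "ok")
  } else if (isTRUE(all.equal(obs, null@mu))) {
    list(z = 0, flag = "degenerate_null")
  } else {
    list(z = sign(obs - null@mu) * Inf, flag = "degenerate_null")
  }
}

#' Summarize degree bins as a data.frame (for audit output)
#'
#' @param bins a \linkS4class{DegreeBins}.
#' @return data.frame with one row per bin: degree range and occupancy.
#' @export
binSummary <- function(bins) {
  stopifnot(methods::is(bins, "DegreeBins"))
  bins@binRanges
}
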