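# Network proximity between a compound's targets S and a disease protein set
# T, with z-scores against the degree-preserving null. Distances are
# unweighted hop counts; the closest metric is
#   d_c(S, T) = (1/|T|) * sum_{t in T} min_{s in S} d(s, t)
# and the shortest metric is the mean of d(s, t) over all pairs.

# Internal: map S and T into the graph, warn about drops, and return the
# |T| x n distance matrix from the mapped disease proteins to all nodes.
.proximitySetup <- function(g, S, T) {
  stopifnot(methods::is(g, "Interactome"))
  Sm <- intersect(.asMembers(S), nodeIds(g))
  Tm <- intersect(.asMembers(T), nodeIds(g))
  nDrop <- (length(.asMembers(S)) - length(Sm)) +
    (length(.asMembers(T)) - length(Tm))
  if (nDrop > 0L) {
    message("proximity: ", nDrop, " node(s) outside the analysis graph dropped")
  }
  if (length(Sm) == 0L || length(Tm) == 0L) stop("disconnected sets")
  list(S = Sm, T = Tm)
}

# Internal statistics on a |T| x |S'| distance submatrix. Unreachable
# (infinite) entries are excluded from the means.
.statClosest <- function(DT) {
  m <- .rowMins(DT)
  m <- m[is.finite(m)]
  if (length(m) == 0L) stop("disconnected sets")
  mean(m)
}

.statShortest <- function(DT) {
  v <- DT[is.finite(DT)]
  if (length(v) == 0L) stop("disconnected sets")
  mean(v)
}

#' Closest network distance between compound targets and disease proteins
#'
#' Mean over disease proteins of the hop distance to the nearest compound
#' target; zero when the disease set is contained in the target set.
#' Disease proteins unreachable from every target are excluded with a
#' warning.
#'
#' @param g an \linkS4class{Interactome}.
#' @param S compound targets (a \linkS4class{TargetSet} or character vector).
#' @param T disease proteins.
#' @return the closest distance (numeric, >= 0).
#' @examples
#' g <- buildInteractome(data.frame(a = c("A", "B", "C"), b = c("B", "C", "D")))
#' distanceClosest(g, "A", "D")  # 3
#' @export
distanceClosest <- function(g, S, T) {
  st <- .proximitySetup(g, S, T)
  DT <- igraph::distances(g@graph, v = st$T, to = st$S)
  m <- .rowMins(DT)
  if (any(!is.finite(m))) {
    warning(sum(!is.finite(m)), " disease protein(s) unreachable; excluded")
  }
  .statClosest(DT)
}

#' Shortest (mean pairwise) network distance
#'
#' Mean hop distance over all (target, disease protein) pairs; unreachable
#' pairs are excluded with a warning.
#'
#' @inheritParams distanceClosest
#' @return the mean pairwise distance (numeric, >= 0).
#' @export
distanceShortest <- function(g, S, T) {
  st <- .proximitySetup(g, S, T)
  DT <- igraph::distances(g@graph, v = st$T, to = st$S)
  if (any(!is.finite(DT))) {
    warning(sum(!is.finite(DT)), " unreachable pair(s) excluded")
  }
  .statShortest(DT)
}

#' Proximity z-score for one metric
#'
#' Observed distance against \code{nReps} degree-matched replacements of the
#' compound target set (the disease set is held fixed). Negative z means
#' closer than degree-matched chance.
#'
#' @inheritParams distanceClosest
#' @param bins \linkS4class{DegreeBins} built on \code{g}.
#' @param metric \code{"closest"} or \code{"shortest"}.
#' @param nReps null replicates (default 1000).
#' @param seed optional seed.
#' @param compound label for the result (default: the name of \code{S}).
#' @return a \linkS4class{ProximityResult} with the requested metric filled;
#'   see \code{\link{networkProximity}} for both at once.
#' @export
proximityZScore <- function(g, S, T, bins, metric = c("closest", "shortest"),
                            nReps = 1000L, seed = NULL, compound = NULL) {
  metric <- match.arg(metric)
  .proximityEngine(g, S, T, bins, metrics = metric, nReps = nReps,
                   seed = seed, compound = compound)
}

#' Proximity z-scores for both metrics
#'
#' Convenience wrapper computing the closest and shortest metrics on a shared
#' set of null replicates.
#'
#' @inheritParams proximityZScore
#' @return a \linkS4class{ProximityResult} with both metrics filled.
#' @examples
#' sc <- syntheticScenario(seed = 3, nNodes = 300, moduleSize = 15)
#' g <- generateInteractome(sc)
#' bins <- makeDegreeBins(g, minBinSize = 50)
#' mod <- plantDiseaseModule(g, sc)
#' networkProximity(g, TargetSet("cmp", members(mod)[1:5]), mod, bins,
#'                  nReps = 100, seed = 11)
#' @export
networkProximity <- function(g, S, T, bins, nReps = 1000L, seed = NULL,
                             compound = NULL) {
  .proximityEngine(g, S, T, bins, metrics = c("closest", "shortest"),
                   nReps = nReps, seed = seed, compound = compound)
}

.proximityEngine <- function(g, S, T, bins, metrics, nReps, seed, compound) {
  if (is.null(compound)) {
    compound <- if (methods::is(S, "TargetSet")) setName(S) else "S"
  }
  st <- .proximitySetup(g, S, T)
  # distances from every disease protein to every node, computed once; each
  # null replicate is then a cheap column lookup
  DTall <- igraph::distances(g@graph, v = st$T)
  dObsC <- if ("closest" %in% metrics) .statClosest(DTall[, st$S, drop = FALSE]) else NA_real_
  dObsS <- if ("shortest" %in% metrics) .statShortest(DTall[, st$S, drop = FALSE]) else NA_real_

  sampler <- .binSampler(st$S, bins)
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  wantC <- "closest" %in% metrics
  wantS <- "shortest" %in% metrics
  reps <- vapply(seq_len(nReps), function(r) {
    if (!is.null(seed)) set.seed(repSeed(seed, r))
    sub <- DTall[, sampler(), drop = FALSE]
    c(closest = if (wantC) .statClosest(sub) else NA_real_,
      shortest = if (wantS) .statShortest(sub) else NA_real_)
  }, numeric(2L))
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  reps <- t(reps)

  nullC <- nullS <- NULL
  zC <- zS <- NA_real_
  flag <- "ok"
  if ("closest" %in% metrics) {
    nullC <- .NullDistribution(reps[, "closest"], seed)
    zr <- .zAgainstNull(dObsC, nullC)
    zC <- zr$z
    if (zr$flag != "ok") flag <- zr$flag
  }
  if ("shortest" %in% metrics) {
    nullS <- .NullDistribution(reps[, "shortest"], seed)
    zr <- .zAgainstNull(dObsS, nullS)
    zS <- zr$z
    if (zr$flag != "ok") flag <- zr$flag
  }
  new("ProximityResult", compound = compound, nS = length(st$S),
      nT = length(st$T), dClosest = dObsC, dShortest = dObsS,
      zClosest = zC, zShortest = zS, nullClosest = nullC,
      nullShortest = nullS, flag = flag)
}

#' Rank compounds by proximity and keep the top k
#'
#' Sorts ascending by \code{zClosest} (most negative = most proximal), with
#' ties broken by \code{dClosest} ascending and then by compound name, and
#' returns the first \code{k} results.
#'
#' @param results list of \linkS4class{ProximityResult}s sharing the same
#'   graph and disease set.
#' @param k how many to keep (default 8).
#' @return the ordered, trimmed list of results; if \code{k} exceeds the
#'   number of results all are returned with a warning.
#' @export
rankCompounds <- function(results, k = 8L) {
  if (length(results) == 0L) return(results)
  z <- vapply(results, function(r) r@zClosest, numeric(1L))
  d <- vapply(results, function(r) r@dClosest, numeric(1L))
  nm <- vapply(results, function(r) r@compound, character(1L))
  ord <- order(z, d, nm)
  if (k > length(results)) {
    warning("k exceeds the number of results; returning all")
    k <- length(results)
  }
  results[ord][seq_len(k)]
}

#' Tabulate proximity results
#'
#' @param results list of \linkS4class{ProximityResult}s.
#' @return data.frame: compound, n_S, n_T, d_closest, z_closest, d_shortest,
#'   z_shortest, abs_z_shortest, mu/sigma of the closest null, n_reps, flag.
#' @export
proximityTable <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(compound = r@compound, n_S = r@nS, n_T = r@nT,
               d_closest = r@dClosest, z_closest = r@zClosest,
               d_shortest = r@dShortest, z_shortest = r@zShortest,
               abs_z_shortest = abs(r@zShortest),
               mu_closest = if (!is.null(r@nullClosest)) r@nullClosest@mu else NA_real_,
               sigma_closest = if (!is.null(r@nullClosest)) r@nullClosest@sigma else NA_real_,
               n_reps = if (!is.null(r@nullClosest)) r@nullClosest@nReps else NA_integer_,
               flag = r@flag, stringsAsFactors = FALSE)
  }))
}
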