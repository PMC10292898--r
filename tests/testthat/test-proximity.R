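toyGraph8 <- function() {
  buildInteractome(rbind(pathEdges(paste0("P", 1:6)),
                         edgesDf(c("P3", "P4"), c("P7", "P8"))))
}

test_that("closest and shortest distances match hand-computed examples", {
  g <- buildInteractome(pathEdges(c("A", "B", "C", "D")))
  expect_identical(distanceClosest(g, "A", "D"), 3)
  expect_identical(distanceClosest(g, c("A", "D"), c("A", "D")), 0)

  star <- buildInteractome(starEdges("X", paste0("L", 1:4)))
  expect_identical(distanceClosest(star, "L1", c("L2", "L3")), 2)

  g3 <- buildInteractome(pathEdges(c("A", "B", "C")))
  expect_identical(distanceShortest(g3, "A", "C"), 2)
  expect_identical(distanceShortest(g3, c("A", "C"), "B"), 1)
})

test_that("distances equal the Floyd-Warshall oracle on random graphs", {
  for (seed in 1:8) {
    e <- randomEdges(40L, 0.08, seed + 300L)
    g <- buildInteractome(e)
    D <- oracleDistances(e, nodeIds(g))
    lcc <- members(largestConnectedComponent(g))
    set.seed(seed)
    S <- sample(lcc, 4L)
    T <- sample(lcc, 5L)
    expect_equal(distanceClosest(g, S, T), oracleClosest(D, S, T))
    expect_equal(distanceShortest(g, S, T), oracleShortest(D, S, T))
  }
})

test_that("closest distance is zero exactly when the disease set is inside the target set", {
  g <- toyGraph8()
  expect_identical(distanceClosest(g, c("P1", "P2", "P3"), c("P1", "P3")), 0)
  expect_gt(distanceClosest(g, c("P1", "P2"), c("P1", "P4")), 0)
})

test_that("adding a target never increases the closest distance", {
  for (seed in 1:5) {
    e <- randomEdges(30L, 0.12, seed + 700L)
    g <- buildInteractome(e)
    lcc <- members(largestConnectedComponent(g))
    set.seed(seed)
    T <- sample(lcc, 4L)
    S <- sample(lcc, 2L)
    extras <- setdiff(lcc, S)
    d <- distanceClosest(g, S, T)
    for (k in 1:5) {
      S <- c(S, extras[k])
      d2 <- distanceClosest(g, S, T)
      expect_lte(d2, d)
      d <- d2
    }
  }
})

test_that("sampled proximity z agrees with exhaustive enumeration on the toy graph", {
  g <- toyGraph8()
  bins <- makeDegreeBins(g, minBinSize = 4L)
  S <- c("P1", "P3")                  # one node from each bin -> 4 x 4 combos
  T <- c("P5", "P6")
  edges <- edgeTable(g)
  D <- oracleDistances(edges, nodeIds(g))

  combos <- enumDegreeMatched(S, bins)
  expect_identical(length(combos), 16L)
  vals <- vapply(combos, function(ids) oracleClosest(D, ids, T), numeric(1L))
  muE <- mean(vals)
  sdE <- sqrt(mean((vals - muE)^2))
  zE <- (oracleClosest(D, S, T) - muE) / sdE

  nReps <- 5000L
  res <- proximityZScore(g, TargetSet("s", S), TargetSet("t", T), bins,
                         metric = "closest", nReps = nReps, seed = 6L)
  expect_equal(res@dClosest, oracleClosest(D, S, T))
  expect_lt(abs(nullMean(res@nullClosest) - muE), 3 * sdE / sqrt(nReps))
  expect_lt(abs(res@zClosest - zE), 3 * sqrt((1 + zE^2 / 2) / nReps))
})

test_that("the convenience wrapper fills both metrics consistently", {
  g <- toyGraph8()
  bins <- makeDegreeBins(g, minBinSize = 4L)
  res <- networkProximity(g, TargetSet("s", c("P1", "P3")),
                          TargetSet("t", c("P5", "P6")), bins,
                          nReps = 400L, seed = 9L)
  expect_lte(res@dClosest, res@dShortest)
  expect_false(is.na(res@zShortest))
  single <- proximityZScore(g, TargetSet("s", c("P1", "P3")),
                            TargetSet("t", c("P5", "P6")), bins,
                            metric = "closest", nReps = 400L, seed = 9L)
  expect_identical(res@zClosest, single@zClosest)
})

test_that("proximity z is stable under node relabeling", {
  e <- randomEdges(40L, 0.1, 77L)
  g <- buildInteractome(e)
  lcc <- members(largestConnectedComponent(g))
  set.seed(1)
  S <- sample(lcc, 4L); T <- sample(lcc, 5L)
  perm <- setNames(sprintf("Q%03d", seq_along(nodeIds(g))), sort(nodeIds(g)))
  e2 <- edgesDf(unname(perm[e$a]), unname(perm[e$b]))
  g2 <- buildInteractome(e2)
  bins <- makeDegreeBins(g, minBinSize = 10L)
  bins2 <- makeDegreeBins(g2, minBinSize = 10L)
  r1 <- proximityZScore(g, S, T, bins, "closest", nReps = 4000L, seed = 3L)
  r2 <- proximityZScore(g2, unname(perm[S]), unname(perm[T]), bins2,
                        "closest", nReps = 4000L, seed = 3L)
  expect_identical(r1@dClosest, r2@dClosest)
  expect_lt(abs(r1@zClosest - r2@zClosest), 0.25)
})

test_that("ranking sorts by z, breaks ties by distance then name, and warns on short lists", {
  mk <- function(name, z, d) {
    new("ProximityResult", compound = name, nS = 3L, nT = 4L, dClosest = d,
        dShortest = d + 1, zClosest = z, zShortest = z,
        nullClosest = NULL, nullShortest = NULL, flag = "ok")
  }
  r <- rankCompounds(list(mk("a", -1, 2), mk("b", -3, 2)), k = 2L)
  expect_identical(vapply(r, function(x) x@compound, character(1L)), c("b", "a"))
  r2 <- rankCompounds(list(mk("a", -2, 1.5), mk("b", -2, 1.2)), k = 1L)
  expect_identical(r2[[1L]]@compound, "b")
  r3 <- rankCompounds(list(mk("b", -2, 1.2), mk("a", -2, 1.2)), k = 1L)
  expect_identical(r3[[1L]]@compound, "a")
  expect_warning(rankCompounds(list(mk("a", -1, 1)), k = 5L), "k exceeds")
})

test_that("unreachable disease proteins are excluded with a warning", {
  g <- buildInteractome(rbind(pathEdges(c("A", "B", "C")), edgesDf("D", "E")))
  expect_warning(d <- distanceClosest(g, "A", c("C", "D")), "unreachable")
  expect_identical(d, 2)
  expect_error(suppressMessages(distanceClosest(g, "A", "X")), "disconnected")
})
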