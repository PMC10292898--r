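test_that("construction canonicalizes IDs, drops self-loops and collapses duplicates", {
  g <- buildInteractome(edgesDf(c("A", "B", "A", "B"), c("B", "A", "A", "C")))
  expect_setequal(nodeIds(g), c("A", "B", "C"))
  expect_identical(edgeCount(g), 2L)
  rep <- loadReport(g)
  expect_identical(rep$nSelfLoopsDropped, 1L)
  expect_identical(rep$nDuplicatesCollapsed, 1L)

  g2 <- buildInteractome(edgesDf(" a ", "b"))
  expect_setequal(nodeIds(g2), c("A", "B"))

  expect_error(buildInteractome(data.frame()), "no edges")
  expect_error(buildInteractome(edgesDf(c("A", ""), c("B", "C"))), "2")
})

test_that("source tags merge across collapsed duplicate edges", {
  g <- buildInteractome(data.frame(a = c("A", "B", "B"), b = c("B", "A", "C"),
                                   src = c("db1", "db2", "db1")))
  et <- edgeTable(g)
  expect_identical(et$source[et$protein_a == "A"], "db1,db2")
})

test_that("largest connected component honors induced-subgraph restriction", {
  g <- buildInteractome(rbind(pathEdges(c("A", "B", "C")), edgesDf("D", "E")))
  expect_identical(componentSize(largestConnectedComponent(g)), 3L)
  expect_setequal(members(largestConnectedComponent(g)), c("A", "B", "C"))
  # A and C disconnect when B is excluded; D-E survives intact
  expect_identical(componentSize(largestConnectedComponent(g, c("A", "C", "D", "E"))), 2L)
  expect_identical(componentSize(largestConnectedComponent(g, "X")), 0L)
})

test_that("component size ties break toward the lexicographically smallest member", {
  g <- buildInteractome(rbind(edgesDf("B", "C"), edgesDf("A", "D")))
  expect_setequal(members(largestConnectedComponent(g)), c("A", "D"))
})

test_that("multi-source BFS distances match the spec examples", {
  g <- buildInteractome(pathEdges(c("A", "B", "C", "D")))
  expect_identical(shortestPathLengthsFrom(g, "A"),
                   c(A = 0L, B = 1L, C = 2L, D = 3L))
  d <- shortestPathLengthsFrom(g, c("A", "D"))
  expect_identical(d[order(names(d))], c(A = 0L, B = 1L, C = 1L, D = 0L))
  expect_error(shortestPathLengthsFrom(g, character(0)), "empty")
})

test_that("BFS distances equal the all-pairs Floyd-Warshall oracle on random graphs", {
  for (seed in 1:10) {
    e <- randomEdges(30L, 0.08, seed)
    g <- buildInteractome(e)
    D <- oracleDistances(e, nodeIds(g))
    set.seed(seed)
    src <- sample(nodeIds(g), 3L)
    d <- shortestPathLengthsFrom(g, src)
    exp <- apply(D[src, , drop = FALSE], 2L, min)
    exp <- exp[is.finite(exp)]
    expect_identical(d[order(names(d))],
                     structure(as.integer(exp[order(names(exp))]),
                               names = sort(names(exp))))
  }
})

test_that("distances obey the triangle inequality on connected triples", {
  for (seed in 1:5) {
    e <- randomEdges(40L, 0.1, seed + 100)
    g <- buildInteractome(e)
    D <- oracleDistances(e, nodeIds(g))
    set.seed(seed)
    for (rep in 1:20) {
      uvw <- sample(nodeIds(g), 3L)
      duw <- D[uvw[1L], uvw[3L]]
      dsum <- D[uvw[1L], uvw[2L]] + D[uvw[2L], uvw[3L]]
      if (is.finite(dsum)) expect_lte(duw, dsum)
    }
  }
})

test_that("degrees satisfy the star example and the handshake lemma", {
  g <- buildInteractome(starEdges("C", paste0("L", 1:4)))
  deg <- nodeDegrees(g)
  expect_identical(unname(deg["C"]), 4L)
  expect_true(all(deg[paste0("L", 1:4)] == 1L))

  gr <- buildInteractome(randomEdges(25L, 0.15, 7L))
  expect_identical(sum(nodeDegrees(gr)), 2L * edgeCount(gr))
})

test_that("rebuilding from the edge table is idempotent", {
  g <- buildInteractome(randomEdges(20L, 0.2, 3L))
  g2 <- buildInteractome(edgeTable(g))
  expect_setequal(nodeIds(g2), nodeIds(g))
  expect_identical(edgeTable(g2), edgeTable(g))
})

test_that("LCC size is monotone non-decreasing under edge addition", {
  e <- randomEdges(25L, 0.06, 11L)
  sizes <- vapply(seq(2L, nrow(e)), function(k) {
    componentSize(largestConnectedComponent(
      buildInteractome(e[seq_len(k), , drop = FALSE])))
  }, integer(1L))
  expect_true(all(diff(sizes) >= 0L))
})

test_that("analysisComponent keeps only the largest component and reports drops", {
  g <- buildInteractome(rbind(pathEdges(c("A", "B", "C")), edgesDf("D", "E")))
  expect_message(lcc <- analysisComponent(g), "2 node")
  expect_setequal(nodeIds(lcc), c("A", "B", "C"))
  expect_identical(loadReport(lcc)$nNodesOutsideLCC, 2L)
})

test_that("edge list TSV round-trips through readEdgeList", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment line", "protein_a\tprotein_b\tsource",
               "a\tb\tdb1", "B\tA\tdb2", "b\tc\tdb1"), tmp)
  g <- readEdgeList(tmp)
  expect_setequal(nodeIds(g), c("A", "B", "C"))
  expect_identical(edgeCount(g), 2L)
  out <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(g, out)
  expect_identical(edgeTable(readEdgeList(out)), edgeTable(g))
})
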