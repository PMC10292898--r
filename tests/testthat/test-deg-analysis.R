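mkExpr <- function(values, nCase = NULL) {
  n <- ncol(values)
  if (is.null(nCase)) nCase <- n %/% 2L
  colnames(values) <- sprintf("S%02d", seq_len(n))
  groups <- rep(c("control", "case"), c(n - nCase, nCase))
  makeExpressionSet(values, setNames(groups, colnames(values)))
}

test_that("DEG thresholds are strict and degenerate genes are handled", {
  vals <- rbind(
    FLAT  = rep(5, 8),                      # identical everywhere -> ns
    EDGE  = rep(c(5, 5.5), each = 4L),      # logFC exactly 0.5 -> ns
    UP    = rep(c(5, 7), each = 4L),        # constant groups, big shift
    NOISY = c(rnorm(4, 5, 0.1), rnorm(4, 8, 0.1)))
  se <- mkExpr(vals)
  degs <- callDEGs(se)
  expect_identical(degs$direction[degs$gene == "FLAT"], "ns")
  expect_identical(degs$p_raw[degs$gene == "FLAT"], 1)
  expect_identical(degs$direction[degs$gene == "EDGE"], "ns")
  expect_equal(degs$logFC[degs$gene == "EDGE"], 0.5)
  expect_identical(degs$direction[degs$gene == "UP"], "up")
  expect_identical(degs$direction[degs$gene == "NOISY"], "up")
  expect_true(all(degs$p_adj >= degs$p_raw))
  expect_error(callDEGs(mkExpr(matrix(rnorm(9), 3,
                                      dimnames = list(paste0("G", 1:3), NULL)),
                               nCase = 1L)),
               "at least 2")
})

test_that("Benjamini-Hochberg adjustment is monotone in the p-value ranks", {
  set.seed(8)
  vals <- matrix(rnorm(200 * 10), 200,
                 dimnames = list(sprintf("G%03d", 1:200), NULL))
  degs <- callDEGs(mkExpr(vals))
  ord <- order(degs$p_raw)
  expect_true(all(diff(degs$p_adj[ord]) >= -1e-12))
  expect_lte(max(degs$p_adj), 1)
  expect_equal(degs$p_adj, p.adjust(degs$p_raw, "BH"))
})

test_that("planted differential expression is recovered with controlled FDR", {
  hits <- 0L; planted <- 0L; falseCalls <- 0L; calls <- 0L
  for (seed in 1:3) {
    sc <- syntheticScenario(seed = seed, nGenes = 400L)
    gen <- generateExpression(sc)
    degs <- callDEGs(gen$se)
    truth <- gen$truth
    called <- degs$gene[degs$direction != "ns"]
    de <- truth$gene[truth$is_de]
    hits <- hits + length(intersect(called, de))
    planted <- planted + length(de)
    falseCalls <- falseCalls + length(setdiff(called, de))
    calls <- calls + length(called)
    # direction of recovered genes matches the planted sign
    m <- merge(degs[degs$direction != "ns", ], truth[truth$is_de, ],
               by = "gene")
    expect_true(all(m$direction.x == m$direction.y))
  }
  expect_gte(hits / planted, 0.95)
  expect_lte(falseCalls / max(calls, 1L), 0.10)
})

test_that("intersection keeps only directional DEGs found in compound targets", {
  degs <- data.frame(gene = c("G1", "G2", "G3"),
                     logFC = c(1, -1, 2), p_raw = 0.001, p_adj = 0.001,
                     direction = c("up", "down", "ns"))
  sets <- list(TargetSet("c1", c("G1", "G3")), TargetSet("c2", c("G1", "G2")))
  out <- intersectTargets(degs, sets)
  expect_identical(out$gene, c("G1", "G2"))
  expect_identical(out$compounds, c("c1,c2", "c2"))
  expect_identical(out$n_compounds, c(2L, 1L))
  expect_identical(nrow(intersectTargets(degs[3, ], sets)), 0L)
})

test_that("hub ranking follows subnetwork degree with alphabetical tie-break", {
  star <- buildInteractome(starEdges("HUB", paste0("L", 1:4)))
  hb <- hubTargets(star, c("HUB", paste0("L", 1:4)), k = 1L)
  expect_identical(hb$gene[hb$selected], "HUB")

  ring <- buildInteractome(cycleEdges(c("C", "A", "B", "D")))
  hb2 <- hubTargets(ring, c("A", "B", "C", "D"), k = 2L)
  expect_identical(hb2$gene[hb2$selected], c("A", "B"))
  expect_error(hubTargets(ring, "A", k = 0L), "positive")
})

test_that("hub degrees equal a brute-force edge recount in the induced subgraph", {
  e <- randomEdges(30L, 0.15, 41L)
  g <- buildInteractome(e)
  set.seed(2)
  genes <- sample(nodeIds(g), 12L)
  hb <- hubTargets(g, genes, k = 5L)
  for (i in seq_len(nrow(hb))) {
    gn <- hb$gene[i]
    cnt <- sum((e$a == gn & e$b %in% genes) | (e$b == gn & e$a %in% genes))
    expect_identical(hb$degree[i], as.integer(cnt))
  }
})

test_that("diagnostic ROC finds the Youden cutoff and corrects orientation", {
  vals <- matrix(c(1, 2, 3, 4), 1L, dimnames = list("G1", NULL))
  se <- mkExpr(vals, nCase = 2L)  # last two samples are cases
  res <- diagnosticROC(se, "G1")
  expect_identical(res@auc, 1)
  expect_identical(res@cutoff, 3)
  expect_identical(res@sensAtCutoff, 1)
  expect_identical(res@specAtCutoff, 1)
  expect_identical(res@direction, "up")

  # swapped labels: same AUC after orientation, direction flips
  seSwap <- makeExpressionSet(
    matrix(c(1, 2, 3, 4), 1L, dimnames = list("G1", sprintf("S%02d", 1:4))),
    setNames(c("case", "case", "control", "control"), sprintf("S%02d", 1:4)))
  res2 <- diagnosticROC(seSwap, "G1")
  expect_identical(res2@auc, 1)
  expect_identical(res2@direction, "down")

  const <- mkExpr(matrix(5, 1L, 6L, dimnames = list("G1", NULL)))
  res3 <- diagnosticROC(const, "G1")
  expect_identical(res3@auc, 0.5)
  expect_identical(res3@flag, "constant_expression")
  expect_true(is.na(res3@cutoff))
})

test_that("diagnostic AUC agrees with the validation-module ROC on the same vectors", {
  set.seed(19)
  vals <- matrix(rnorm(20, 7), 1L, dimnames = list("G1", NULL))
  se <- mkExpr(vals, nCase = 10L)
  res <- diagnosticROC(se, "G1")
  pos <- sampleGroups(se) == "case"
  a <- rocAuc(as.numeric(vals), pos)@auc
  expect_equal(res@auc, max(a, 1 - a))
  expect_gte(res@auc, 0.5)
})

test_that("high-accuracy biomarkers are flagged at AUC > 0.9 with a sensible cutoff", {
  set.seed(23)
  vals <- matrix(c(rnorm(13, 7, 0.4), rnorm(13, 9.5, 0.4)), 1L,
                 dimnames = list("MARKER", NULL))
  se <- mkExpr(vals, nCase = 13L)
  res <- diagnosticROC(se, "MARKER")
  expect_true(res@highAccuracy)
  expect_gt(res@cutoff, min(vals))
  expect_lt(res@cutoff, max(vals))
  skip_if_not_installed("pROC")
  pr <- pROC::roc(response = sampleGroups(se) == "case",
                  predictor = as.numeric(vals), direction = "<", quiet = TRUE)
  expect_equal(res@auc, as.numeric(pROC::auc(pr)))
})
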