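test_that("interactome generation is connected, deterministic and heavy-tailed", {
  scSmall <- syntheticScenario(seed = 2, nNodes = 10L, moduleSize = 4L)
  g10 <- generateInteractome(scSmall)
  expect_identical(nodeCount(g10), 10L)
  expect_identical(componentSize(largestConnectedComponent(g10)), 10L)

  sc <- syntheticScenario(seed = 4)
  g1 <- generateInteractome(sc)
  g2 <- generateInteractome(sc)
  expect_identical(edgeTable(g1), edgeTable(g2))

  ratios <- vapply(1:5, function(s) {
    g <- generateInteractome(syntheticScenario(seed = s))
    deg <- nodeDegrees(g)
    max(deg) / median(deg)
  }, numeric(1L))
  expect_true(all(ratios >= 10))
})

test_that("the planted disease module is connected and of the requested size", {
  sc <- syntheticScenario(seed = 6, nNodes = 500L, moduleSize = 25L)
  g <- generateInteractome(sc)
  mod <- plantDiseaseModule(g, sc)
  expect_identical(length(members(mod)), 25L)
  expect_identical(componentSize(largestConnectedComponent(g, mod)), 25L)
})

test_that("the planted module is significantly more connected than matched chance", {
  hits <- vapply(1:6, function(s) {
    sc <- syntheticScenario(seed = s)
    g <- generateInteractome(sc)
    bins <- makeDegreeBins(g)
    mod <- plantDiseaseModule(g, sc)
    res <- lccZScore(g, mod, bins, nReps = 300L, seed = s)
    abs(res@z) > 1.70
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})

test_that("compound planting honors set sizes, truth labels and the overlap rule", {
  sc <- syntheticScenario(seed = 9, nNodes = 800L, moduleSize = 25L)
  g <- generateInteractome(sc)
  bins <- makeDegreeBins(g)
  mod <- plantDiseaseModule(g, sc)
  cmp <- plantCompounds(g, mod, bins, sc)
  expect_identical(length(cmp$sets), 30L)
  expect_true(all(lengths(lapply(cmp$sets, members)) == 10L))
  expect_identical(sum(cmp$truth$is_signal), 3L)
  hood <- union(members(mod), names(shortestPathLengthsFrom(g, mod))[
    shortestPathLengthsFrom(g, mod) <= 1L])
  for (i in which(cmp$truth$is_signal)) {
    nIn <- sum(members(cmp$sets[[i]]) %in% hood)
    expect_gte(nIn, round(0.7 * 10))
  }
})

test_that("null compounds mirror the degree profile of their signal template", {
  sc <- syntheticScenario(seed = 12, nNodes = 800L, moduleSize = 25L)
  g <- generateInteractome(sc)
  bins <- makeDegreeBins(g)
  mod <- plantDiseaseModule(g, sc)
  cmp <- plantCompounds(g, mod, bins, sc)
  idx <- bins@binIndex
  profile <- function(s) tabulate(idx[members(s)], nbins = length(bins@binMembers))
  for (j in which(!cmp$truth$is_signal)) {
    template <- cmp$sets[[(j - 4L) %% 3L + 1L]]
    expect_identical(profile(cmp$sets[[j]]), profile(template))
  }
})

test_that("expression generation plants the stated effect with Gaussian noise", {
  sc <- syntheticScenario(seed = 3, nGenes = 600L, nPerGroup = 40L)
  gen <- generateExpression(sc)
  x <- exprValues(gen$se)
  grp <- sampleGroups(gen$se)
  diff <- rowMeans(x[, grp == "case"]) - rowMeans(x[, grp == "control"])
  truth <- gen$truth
  expect_identical(sum(truth$is_de), 60L)
  planted <- truth$is_de
  signedEffect <- ifelse(truth$direction == "up", 2, -2)[planted]
  # group-mean differences concentrate near the planted effect (se ~ 0.11)
  expect_lt(max(abs(diff[planted] - signedEffect)), 0.5)
  expect_lt(max(abs(diff[!planted])), 0.5)
  expect_lt(abs(mean(diff[!planted])), 0.05)
})

test_that("association generation yields labeled, duplicate-free benchmark pairs", {
  sc <- syntheticScenario(seed = 7, nNodes = 500L, moduleSize = 20L,
                          nSignal = 2L, nNull = 3L)
  st <- simulateStudy(sc, minBinSize = 60L, nDiseasesPerCompound = 10L)
  pairs <- st$associations$pairs
  expect_identical(nrow(pairs), 20L)
  expect_identical(anyDuplicated(pairs[, c("compound", "disease")]), 0L)
  expect_identical(unname(table(pairs$label)["therapeutic"]), 10L)
  expect_setequal(names(st$associations$diseaseSets), pairs$disease)
})

test_that("generator truth predicts the DEG-target intersection", {
  sc <- syntheticScenario(seed = 11, nNodes = 600L, moduleSize = 20L,
                          nGenes = 400L)
  st <- simulateStudy(sc, minBinSize = 80L, nDiseasesPerCompound = 4L)
  degs <- callDEGs(st$expression$se)
  inter <- intersectTargets(degs, st$compounds$sets)
  allTargets <- unique(unlist(lapply(st$compounds$sets, members)))
  truthInter <- intersect(
    st$expression$truth$gene[st$expression$truth$is_de], allTargets)
  # the planted effect (4 noise sds) makes recovery essentially certain;
  # false positives are BH-limited
  expect_true(all(truthInter %in% inter$gene))
  expect_lte(nrow(inter) - length(truthInter), 2L)
})

test_that("the written bundle round-trips through the file readers", {
  sc <- syntheticScenario(seed = 8, nNodes = 300L, moduleSize = 15L,
                          nSignal = 2L, nNull = 4L, nGenes = 120L,
                          nPerGroup = 6L)
  dir <- withr::local_tempdir()
  st <- writeSyntheticBundle(sc, dir, minBinSize = 50L,
                             nDiseasesPerCompound = 4L)
  g <- readEdgeList(file.path(dir, "edges.tsv"))
  expect_identical(edgeTable(g), edgeTable(st$interactome))
  sets <- readTargetSets(file.path(dir, "compound_targets.gmt"))
  expect_identical(names(sets), names(st$compounds$sets))
  dz <- readNodeSet(file.path(dir, "disease_proteins.txt"))
  expect_setequal(members(dz), members(st$module))
  se <- readExpressionTSV(file.path(dir, "expression.tsv"),
                          file.path(dir, "samples.tsv"))
  expect_equal(exprValues(se), exprValues(st$expression$se))
  pairs <- readAssociations(file.path(dir, "associations.tsv"))
  expect_equal(pairs, st$associations$pairs, ignore_attr = TRUE)
})
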