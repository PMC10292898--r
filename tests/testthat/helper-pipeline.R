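# Small synthetic bundle + configuration shared by the pipeline and
# determinism tests.

smallBundle <- function(dir, seed = 14L) {
  sc <- syntheticScenario(seed = seed, nNodes = 400L, moduleSize = 18L,
                          nSignal = 2L, nNull = 6L, nGenes = 150L,
                          nPerGroup = 8L)
  writeSyntheticBundle(sc, dir, minBinSize = 60L, nDiseasesPerCompound = 4L)
}

smallConfig <- function(dir, out, ...) {
  runConfig(edgeFile = file.path(dir, "edges.tsv"),
            targetsFile = file.path(dir, "compound_targets.gmt"),
            diseaseFile = file.path(dir, "disease_proteins.txt"),
            associationFile = file.path(dir, "associations.tsv"),
            diseaseSetsFile = file.path(dir, "disease_sets.gmt"),
            exprFile = file.path(dir, "expression.tsv"),
            sampleSheet = file.path(dir, "samples.tsv"),
            nReps = 100L, minBinSize = 60L, kTopCompounds = 4L, kHubs = 6L,
            lccScope = "full", seed = 21L, outputDir = out, ...)
}
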