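# Shared fixtures, built once per test run and memoized. All fixtures are
# generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixtureDataset <- function() {
  if (is.null(.fixtures$ds))
    .fixtures$ds <- generateDataset(
      syntheticConfig(nPositive = 114, nNegative = 86, patchSize = 32,
                      seed = 21))
  .fixtures$ds
}

# A bundle jointly trained on the fixture dataset, used by tests that need
# a functioning encoder/generator/classifier.
fixtureTrained <- function() {
  if (is.null(.fixtures$trained)) {
    ds <- fixtureDataset()
    tj <- trainJoint(networkBundle(seed = 3), ds, epochs = 40L, seed = 5L)
    .fixtures$trained <- tj
  }
  .fixtures$trained
}

# Small train/test pair for loop tests (16 px to keep loops fast).
fixtureSplitData <- function() {
  if (is.null(.fixtures$split)) {
    ds <- generateDataset(syntheticConfig(nPositive = 140, nNegative = 110,
                                          patchSize = 16, seed = 33))
    ds <- stratifiedSplit(ds, 0.7, seed = 34)
    .fixtures$split <- list(train = ds[sampleSplits(ds) == "train"],
                            test = ds[sampleSplits(ds) == "test"])
  }
  .fixtures$split
}
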