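test_that("syntheticConfig validates its inputs", {
  expect_error(syntheticConfig(nPositive = 0), "positive")
  expect_error(syntheticConfig(nNegative = 0), "positive")
  expect_error(syntheticConfig(patchSize = 4), "at least 8")
  expect_error(syntheticConfig(textureContrast = 0), "0, 1")
  expect_error(syntheticConfig(invalidFraction = 1), "0, 1")
})

test_that("generateDataset returns the requested composition, deterministically", {
  cfg <- syntheticConfig(nPositive = 20, nNegative = 15, patchSize = 16,
                         seed = 7)
  ds <- generateDataset(cfg)
  expect_s4_class(ds, "ImageSet")
  expect_length(ds, 35L)
  expect_equal(sum(sampleLabels(ds) == "positive"), 20L)
  expect_equal(sum(sampleLabels(ds) == "negative"), 15L)
  expect_false(anyDuplicated(sampleIds(ds)) > 0)
  rng <- range(unlist(ds@images))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
  # bit-identical regeneration under the same seed
  ds2 <- generateDataset(cfg)
  expect_identical(ds@images, ds2@images)
  expect_identical(ds@manifest, ds2@manifest)
  # a different seed changes the pixels
  ds3 <- generateDataset(syntheticConfig(nPositive = 20, nNegative = 15,
                                         patchSize = 16, seed = 8))
  expect_false(identical(ds@images, ds3@images))
})

test_that("invalid injection is screened out at the expected rate", {
  cfg <- syntheticConfig(nPositive = 570, nNegative = 430, patchSize = 16,
                         invalidFraction = 0.1, seed = 5)
  ds <- generateDataset(cfg)
  expect_length(ds, 1100L)
  sc <- screenInvalid(ds)
  expect_length(sc$rejected, 100L)   # exactly the injected blanks
  expect_true(all(grepl("^inv", sampleIds(sc$rejected))))
  # partition invariant: valid and rejected tile the input
  expect_equal(length(sc$valid) + length(sc$rejected), length(ds))
  expect_length(intersect(sampleIds(sc$valid), sampleIds(sc$rejected)), 0L)
})

test_that("screenInvalid rejects blank and saturated images, keeps textured ones", {
  blank <- array(1, dim = c(16, 16, 3))
  textured <- getImage(fixtureDataset(), 1)
  x <- ImageSet(list(blank, textured), ids = c("white", "tex"))
  sc <- screenInvalid(x)
  expect_identical(sampleIds(sc$rejected), "white")
  expect_identical(sampleIds(sc$valid), "tex")
  expect_error(screenInvalid(x, varianceFloor = -1), "non-negative")
})

test_that("resizeImage obeys the identity, range and constancy contracts", {
  a <- getImage(fixtureDataset(), 1)            # 32 x 32
  expect_identical(resizeImage(a, 32), a)       # identity resize untouched
  up <- resizeImage(a, 48)
  expect_equal(dim(up), c(48L, 48L, 3L))
  expect_true(all(up >= 0 & up <= 1))
  flat <- array(0.25, dim = c(16, 16, 3))
  expect_equal(as.numeric(resizeImage(flat, 40)),
               rep(0.25, 40 * 40 * 3), tolerance = 1e-6)
  expect_error(resizeImage(a, 4), "at least 8")
  # ImageSet method resizes every sample
  ds <- resizeImage(fixtureDataset()[1:3], 16)
  expect_true(all(vapply(ds@images, function(im) all(dim(im) == c(16, 16, 3)),
                         logical(1))))
})

test_that("augmentD4 produces the exact 8-element orbit", {
  ds <- fixtureDataset()[1:4]
  aug <- augmentD4(ds)
  expect_length(aug, 32L)
  expect_equal(sum(aug@manifest$provenance == "augmented"), 28L)
  expect_equal(sum(aug@manifest$provenance == "real"), 4L)
  # labels and splits inherited
  expect_equal(unique(aug@manifest$label[1:8]), ds@manifest$label[1])
  # rotational symmetry does not reduce the record count
  sym <- array(0.5, dim = c(8, 8, 3))
  expect_length(augmentD4(ImageSet(list(sym), ids = "sym")), 8L)
})

test_that("the D4 orbit is closed: re-augmenting any member regenerates the same multiset", {
  set.seed(42)
  a <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  orbit1 <- augmentD4(ImageSet(list(a), ids = "x"))
  key <- function(im) paste(signif(as.numeric(im), 12), collapse = ",")
  ms1 <- sort(vapply(orbit1@images, key, character(1)))
  # start over from the 3rd member of the orbit
  b <- orbit1@images[[3L]]
  orbit2 <- augmentD4(ImageSet(list(b), ids = "y"))
  ms2 <- sort(vapply(orbit2@images, key, character(1)))
  expect_identical(ms1, ms2)
})

test_that("addNoiseSubset perturbs exactly the requested count, in place", {
  ds <- fixtureDataset()[1:40]
  expect_identical(addNoiseSubset(ds, fraction = 0, seed = 1)@images, ds@images)
  expect_identical(addNoiseSubset(ds, fraction = 1, sigma = 0, seed = 1)@images,
                   ds@images)
  noisy <- addNoiseSubset(ds, fraction = 0.25, sigma = 0.05, seed = 9)
  expect_length(noisy, 40L)
  changed <- vapply(seq_len(40), function(i)
    !identical(noisy@images[[i]], ds@images[[i]]), logical(1))
  expect_equal(sum(changed), 10L)
  expect_true(all(unlist(noisy@images) >= 0 & unlist(noisy@images) <= 1))
  expect_identical(addNoiseSubset(ds, 0.25, 0.05, seed = 9)@images,
                   noisy@images)
  expect_error(addNoiseSubset(ds, fraction = 1.5), "0, 1")
})

test_that("stratifiedSplit keeps per-class ratios within one sample", {
  ds <- fixtureDataset()   # 114 positive / 86 negative
  sp <- stratifiedSplit(ds, 0.7, seed = 4)
  man <- sampleManifest(sp)
  for (cl in c("positive", "negative")) {
    nCl <- sum(man$label == cl)
    nTr <- sum(man$label == cl & man$split == "train")
    expect_lte(abs(nTr - 0.7 * nCl), 1)
  }
  expect_true(all(man$split %in% c("train", "test")))
  # exact small case: 10 + 10 at 0.7 gives 7 + 7 in train
  small <- ImageSet(rep(list(array(0.5, c(8, 8, 3))), 20),
                    ids = sprintf("s%02d", 1:20),
                    labels = rep(c("positive", "negative"), each = 10))
  spSmall <- stratifiedSplit(small, 0.7, seed = 1)
  tab <- table(sampleManifest(spSmall)$label,
               sampleManifest(spSmall)$split)
  expect_equal(unname(tab["positive", "train"]), 7)
  expect_equal(unname(tab["negative", "train"]), 7)
  # determinism and error cases
  expect_identical(stratifiedSplit(ds, 0.7, seed = 4)@manifest, sp@manifest)
  onlyPos <- ImageSet(list(array(0.5, c(8, 8, 3))), ids = "a",
                      labels = "positive")
  expect_error(stratifiedSplit(onlyPos, 0.7), "has no samples")
  expect_error(stratifiedSplit(ds, 1.0), "0, 1")
})

test_that("classes are separable by a mean-texture probe at full contrast", {
  ds <- generateDataset(syntheticConfig(nPositive = 285, nNegative = 215,
                                        textureContrast = 1, seed = 13))
  f <- textureFeatures(ds)
  y <- as.integer(sampleLabels(ds) == "positive")
  fit <- suppressWarnings(stats::glm(y ~ f, family = stats::binomial))
  acc <- mean((stats::fitted(fit) > 0.5) == y)
  expect_gt(acc, 0.9)
})

test_that("ImageSet validity catches malformed objects", {
  img <- array(0.5, c(8, 8, 3))
  expect_error(ImageSet(list(img, img), ids = c("a", "a")), "unique")
  expect_error(ImageSet(list(img), ids = "a", labels = "tumor"),
               "negative/positive/unknown")
  expect_error(new("ImageSet", images = list(array(2, c(8, 8, 3))),
                   manifest = data.frame(id = "a", label = "unknown",
                                         split = "unassigned",
                                         provenance = "real")),
               "0, 1")
})
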