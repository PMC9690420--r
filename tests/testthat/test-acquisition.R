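test_that("BALD uncertainty matches its closed-form examples", {
  # all passes identical: mutual information vanishes
  expect_equal(baldUncertainty(matrix(c(0.3, 0.7), 4, 2, byrow = TRUE)), 0,
               tolerance = 1e-12)
  expect_equal(baldUncertainty(rbind(c(1, 0), c(0, 1))), log(2),
               tolerance = 1e-9)
  st <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.1, 0.9))
  expect_equal(baldUncertainty(st), bruteBald(st), tolerance = 1e-12)
  expect_equal(round(baldUncertainty(st), 4), 0.2454)
  expect_error(baldUncertainty(rbind(c(0.5, 0.4))), "sum to 1")
})

test_that("entropy and least-confidence scores match direct evaluation", {
  expect_equal(entropyScore(c(0.5, 0.5)), log(2))
  expect_equal(confidenceScore(c(0.5, 0.5)), 0.5)
  expect_equal(entropyScore(c(1, 0)), 0)
  expect_equal(confidenceScore(c(1, 0)), 0)
  expect_equal(entropyScore(c(0.8, 0.2)),
               -(0.8 * log(0.8) + 0.2 * log(0.2)), tolerance = 1e-12)
  expect_equal(confidenceScore(c(0.8, 0.2)), 0.2)
})

test_that("class centroids are per-class arithmetic means", {
  z <- rbind(c(0, 0), c(2, 2), c(5, 1))
  cl <- c("negative", "negative", "positive")
  cc <- classCentroids(z, cl)
  expect_equal(unname(cc$centroids["negative", ]), c(1, 1))
  expect_equal(unname(cc$centroids["positive", ]), c(5, 1))
  expect_equal(unname(cc$counts), c(2L, 1L))
  set.seed(5)
  zr <- matrix(rnorm(40), 20, 2)
  clr <- rep(c("negative", "positive"), 10)
  ccr <- classCentroids(zr, clr)
  expect_equal(unname(ccr$centroids["positive", ]),
               colMeans(zr[clr == "positive", ]))
  expect_error(classCentroids(zr[clr == "negative", , drop = FALSE],
                              rep("negative", 10))$centroids, NA)
})

test_that("centroid distances are Euclidean, in class order", {
  cents <- rbind(negative = c(0, 0), positive = c(1, 1))
  d <- centroidDistances(c(3, 4), cents)
  expect_equal(unname(d["negative"]), 5)
  expect_equal(unname(d["positive"]), sqrt(4 + 9))
  expect_equal(unname(centroidDistances(c(1, 1), cents)["positive"]), 0)
  expect_error(centroidDistances(c(1, 2, 3), cents), "mismatch")
  set.seed(6)
  z <- rnorm(4); M <- matrix(rnorm(8), 2, 4)
  expect_equal(unname(centroidDistances(z, M)),
               apply(M, 1, function(r) sqrt(sum((z - r)^2))))
})

test_that("diversity score follows the z-score/softmax/entropy pipeline", {
  expect_equal(diversityScore(c(3.7), k = 1), 0)
  # equidistant: zero-variance rule gives the uniform maximum log k
  expect_equal(diversityScore(c(2, 2), k = 2), log(2))
  # z-scores (-1, 1), softmax (0.1192, 0.8808), entropy 0.36533
  expect_equal(diversityScore(c(1, 3), k = 2), 0.3653, tolerance = 1e-4)
  expect_equal(diversityScore(c(1, 3), k = 2), bruteDiversity(c(1, 3), 2),
               tolerance = 1e-12)
  expect_error(diversityScore(c(1, 2), k = 3), "out of range")
  # location invariance: adding a constant leaves the score unchanged
  set.seed(7)
  for (i in 1:20) {
    d <- runif(4, 0, 10)
    expect_equal(diversityScore(d, 3), diversityScore(d + 5, 3),
                 tolerance = 1e-9)
  }
})

test_that("min-max scaling maps to [0,1] with the degenerate all-zero rule", {
  expect_equal(minmaxScale(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(minmaxScale(c(2, 2, 2)), c(0, 0, 0))
  expect_error(minmaxScale(numeric()), "empty")
  set.seed(8)
  v <- rnorm(50)
  s <- minmaxScale(v)
  expect_equal(s[which.min(v)], 0)
  expect_equal(s[which.max(v)], 1)
  expect_identical(order(s), order(v))
})

test_that("combined score respects theta and its limit cases", {
  u <- c(0.1, 0.9, 0.4); d <- c(0.8, 0.2, 0.6)
  expect_equal(combinedScore(u, d, theta = 1), u)
  expect_equal(combinedScore(u, d, theta = 0), d)
  expect_equal(combinedScore(u, d, theta = 0.5), 0.5 * u + 0.5 * d)
  expect_error(combinedScore(u, d[1:2], 0.5), "mismatch")
  expect_error(combinedScore(u, d, 1.5), "0, 1")
  # monotone in each argument
  u2 <- u; u2[1] <- u2[1] + 0.05
  expect_gt(combinedScore(u2, d, 0.5)[1], combinedScore(u, d, 0.5)[1])
})

test_that("rankAndSelect returns the top n with lexicographic tie-break", {
  sc <- data.frame(sample_id = c("a", "b", "c"),
                   combined = c(0.9, 0.1, 0.5), stringsAsFactors = FALSE)
  expect_identical(rankAndSelect(sc, 2), c("a", "c"))
  expect_identical(sort(rankAndSelect(sc, 3)), c("a", "b", "c"))
  tie <- data.frame(sample_id = c("z", "a"), combined = c(0.5, 0.5))
  expect_identical(rankAndSelect(tie, 1), "a")
  expect_error(rankAndSelect(sc, 4), "exceeds")
})

test_that("BALD is bounded by the entropy of the mean prediction", {
  set.seed(9)
  for (i in 1:200) {
    st <- randomStack(sample(2:8, 1), sample(2:4, 1))
    mi <- baldUncertainty(st)
    expect_gte(mi, 0)
    expect_lte(mi, entropyScore(colMeans(st)) + 1e-12)
  }
})

test_that("scorePool produces coherent ScoreRecords for every strategy", {
  tj <- fixtureTrained()
  ds <- fixtureDataset()
  labeled <- ds[1:40]
  cands <- ds[151:180]
  cands@manifest$label <- "unknown"
  cfg <- acquisitionConfig(T = 5, poolSize = 30, nSelect = 5)
  for (strat in c("combined", "bald", "entropy", "confidence", "random")) {
    sc <- scorePool(tj$bundle, cands, labeled, cfg, strategy = strat, seed = 3)
    expect_equal(nrow(sc), 30L)
    expect_true(all(sc$unc_scaled >= 0 & sc$unc_scaled <= 1))
    expect_true(all(sc$div_scaled >= 0 & sc$div_scaled <= 1))
    if (strat == "combined")
      expect_equal(sc$combined,
                   0.5 * sc$unc_scaled + 0.5 * sc$div_scaled,
                   tolerance = 1e-12)
  }
  # theta = 1 ranks exactly like the raw BALD scores
  cfg1 <- acquisitionConfig(T = 5, theta = 1, poolSize = 30, nSelect = 5)
  scC <- scorePool(tj$bundle, cands, labeled, cfg1, "combined", seed = 3)
  scB <- scorePool(tj$bundle, cands, labeled, cfg1, "bald", seed = 3)
  expect_identical(rankAndSelect(scC, 5), rankAndSelect(scB, 5))
})
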