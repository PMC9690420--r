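test_that("the simulated oracle answers from ground truth and audits queries", {
  ds <- fixtureDataset()
  orc <- simulatedOracle(ds)
  ids <- sampleIds(ds)[c(1, 120)]
  labs <- queryLabel(orc, ids)
  expect_identical(labs, unname(sampleLabels(ds)[ids]))
  expect_equal(oracleCount(orc), 2L)
  queryLabel(orc, sampleIds(ds)[5])
  expect_equal(oracleCount(orc), 3L)
  expect_error(queryLabel(orc, "nonexistent"), "no label")
})

test_that("samplePool draws without replacement, deterministically", {
  ds <- fixtureDataset()
  st <- loopState(ds[1:50], ds[51:200])
  cand <- samplePool(st, 30, seed = 5)
  expect_length(cand, 30L)
  expect_false(anyDuplicated(cand) > 0)
  expect_true(all(cand %in% sampleIds(ds[51:200])))
  expect_identical(samplePool(st, 30, seed = 5), cand)
  # requesting more than the pool returns the whole pool
  expect_setequal(samplePool(st, 1000, seed = 1), sampleIds(ds[51:200]))
  empty <- loopState(ds[1:50], ds[0])
  expect_length(samplePool(empty, 10, seed = 1), 0L)
})

test_that("incorporate moves ids and keeps the pools disjoint", {
  ds <- fixtureDataset()
  st <- loopState(ds[1:50], ds[51:200])
  sel <- sampleIds(ds)[51:60]
  labs <- unname(sampleLabels(ds)[sel])
  st2 <- incorporate(st, sel, labs)
  expect_length(st2$labeled, 60L)
  expect_length(st2$unlabeled, 140L)
  expect_length(intersect(sampleIds(st2$labeled), sampleIds(st2$unlabeled)), 0L)
  expect_identical(unname(sampleLabels(st2$labeled)[sel]), labs)
  # with reconstructions the labeled pool grows by 2n
  recon <- ds[61:70]
  recon@manifest$id <- paste0(recon@manifest$id, "_re")
  recon@manifest$provenance <- "reconstructed"
  st3 <- incorporate(st, sel, labs, recon)
  expect_length(st3$labeled, 70L)
  # no-op and error cases
  expect_identical(incorporate(st, character(), character())$labeled@manifest,
                   st$labeled@manifest)
  expect_error(incorporate(st, "pos00001", "positive"), "not in the unlabeled")
  expect_error(loopState(ds[1:50], ds[50:60]), "disjoint")
})

test_that("reconstructSelected yields one labeled, bounded twin per sample", {
  tj <- fixtureTrained()
  ds <- fixtureDataset()[31:35]
  labs <- unname(sampleLabels(ds))
  rec <- reconstructSelected(tj$bundle, ds, labs, seed = 2)
  expect_length(rec, 5L)
  expect_identical(unname(sampleLabels(rec)), labs)
  expect_true(all(rec@manifest$provenance == "reconstructed"))
  expect_true(all(unlist(rec@images) >= 0 & unlist(rec@images) <= 1))
  expect_equal(dim(rec@images[[1]]), dim(ds@images[[1]]))
  expect_error(reconstructSelected(networkBundle(seed = 1), ds, labs),
               "trained")
})

test_that("maxIterations = 0 returns a trained classifier and empty history", {
  d <- fixtureSplitData()
  cfg <- loopConfig(strategy = "random", maxIterations = 0L,
                    initialEpochs = 3L, seed = 7)
  run <- runActiveLearning(cfg, d$train, d$test)
  expect_s4_class(run, "ActiveRun")
  expect_equal(nrow(runHistory(run)), 0L)
  expect_true(run@bundle@trained)
  expect_equal(oracleQueries(run), 0L)
})

test_that("loop bookkeeping follows the 2n (generative) and n (baseline) arithmetic", {
  d <- fixtureSplitData()
  acq <- acquisitionConfig(T = 3, poolSize = 60, nSelect = 8)
  base <- list(acquisition = acq, maxIterations = 3L, initialEpochs = 4L,
               retrainEpochs = 1L, seed = 19)
  runG <- runActiveLearning(do.call(loopConfig, c(strategy = "combined", base)),
                            d$train, d$test)
  runB <- runActiveLearning(do.call(loopConfig, c(strategy = "entropy", base)),
                            d$train, d$test)
  hG <- runHistory(runG); hB <- runHistory(runB)
  expect_equal(nrow(hG), 3L)
  expect_equal(nrow(hB), 3L)
  n0 <- hG$n_labeled[1] - 2 * 8
  expect_equal(hG$n_labeled, n0 + 2 * 8 * (1:3))        # originals + twins
  expect_equal(hB$n_labeled, hB$n_labeled[1] - 8 + 8 * (1:3))  # originals only
  expect_equal(hG$n_labeled_originals, hB$n_labeled_originals)
  expect_equal(oracleQueries(runG), 24L)                # query audit
  expect_equal(oracleQueries(runB), 24L)
  expect_true(all(diff(hG$labeled_fraction) > 0))
})

test_that("a run replayed from the same configuration is identical", {
  d <- fixtureSplitData()
  cfg <- loopConfig(strategy = "combined",
                    acquisition = acquisitionConfig(T = 3, poolSize = 40,
                                                    nSelect = 5),
                    maxIterations = 2L, initialEpochs = 3L,
                    retrainEpochs = 1L, seed = 77)
  r1 <- runActiveLearning(cfg, d$train, d$test)
  r2 <- runActiveLearning(cfg, d$train, d$test)
  expect_identical(runHistory(r1), runHistory(r2))
  expect_identical(r1@bundle@classifier$layers, r2@bundle@classifier$layers)
})

test_that("with theta = 1 the combined loop reduces to the BALD+reconstruction arm", {
  d <- fixtureSplitData()
  mk <- function(strategy) loopConfig(
    strategy = strategy,
    acquisition = acquisitionConfig(T = 3, theta = 1, poolSize = 50,
                                    nSelect = 6),
    maxIterations = 2L, initialEpochs = 3L, retrainEpochs = 1L, seed = 55)
  rc <- runActiveLearning(mk("combined"), d$train, d$test)
  rb <- runActiveLearning(mk("gan_bald"), d$train, d$test)
  expect_identical(runHistory(rc)$selected_ids, runHistory(rb)$selected_ids)
  expect_identical(runHistory(rc)$accuracy, runHistory(rb)$accuracy)
})

test_that("the loop stops when the label budget or the pool is exhausted", {
  d <- fixtureSplitData()
  cfg <- loopConfig(strategy = "random",
                    acquisition = acquisitionConfig(poolSize = 40, nSelect = 10),
                    maxIterations = 5L, labelBudget = 25,
                    initialEpochs = 2L, retrainEpochs = 1L, seed = 3)
  run <- runActiveLearning(cfg, d$train, d$test)
  expect_equal(nrow(runHistory(run)), 2L)   # third batch would exceed 25
  expect_lte(oracleQueries(run), 25L)
})
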