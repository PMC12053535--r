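test_that("cosine decay hits its endpoints and midpoint and never increases", {
  expect_equal(cosineLR(0, 100000), 1e-3)
  expect_equal(cosineLR(100000, 100000), 1e-5)
  expect_equal(cosineLR(50000, 100000), (1e-3 + 1e-5) / 2)  # 5.05e-4
  lr <- cosineLR(seq(0, 1000, by = 10), 1000)
  expect_true(all(diff(lr) <= 0))
  expect_error(cosineLR(-1, 100), "out of range")
  expect_error(cosineLR(101, 100), "out of range")
})

test_that("task2Inputs stacks channels and flags the prior masks", {
  pair <- generatePairedPhantom(shape = c(16, 16, 8), seed = 6)
  stack <- task2Inputs(pair$mid$volume, pair$pre$volume, pair$pre$mask)
  expect_identical(dim(stack), c(16L, 16L, 8L, 4L))
  expect_identical(stack[, , , 1], volData(pair$mid$volume))
  expect_identical(stack[, , , 2], volData(pair$pre$volume))
  expect_true(all(stack[, , , 3] == (maskLabels(pair$pre$mask) == 1)))
  expect_true(all(stack[, , , 4] == (maskLabels(pair$pre$mask) == 2)))
  expect_identical(attr(stack, "normalizeChannels"),
                   c(TRUE, TRUE, FALSE, FALSE))

  # empty prior mask: both mask channels all zero
  emptyPrior <- LabelMask(array(0L, c(16, 16, 8)))
  stack0 <- task2Inputs(pair$mid$volume, pair$pre$volume, emptyPrior)
  expect_true(all(stack0[, , , 3:4] == 0))

  # grid mismatch is an error
  small <- Volume(array(0, c(8, 8, 8)))
  expect_error(task2Inputs(small, pair$pre$volume, pair$pre$mask),
               "grid mismatch")
})

test_that("selective normalization leaves binary prior channels untouched", {
  pair <- generatePairedPhantom(shape = c(16, 16, 8), seed = 7)
  stack <- task2Inputs(pair$mid$volume, pair$pre$volume, pair$pre$mask)
  norm <- GTVseg:::.normalizeStackPatch(stack,
                                        attr(stack, "normalizeChannels"))
  expect_identical(norm[, , , 3], stack[, , , 3])
  expect_identical(norm[, , , 4], stack[, , , 4])
  expect_lt(abs(mean(norm[, , , 1])), 1e-6)
  expect_lt(abs(mean(norm[, , , 2])), 1e-6)
  expect_false(identical(norm[, , , 1], stack[, , , 1]))
})

test_that("training reduces the loss and is reproducible from its seed", {
  dir <- withr::local_tempdir()
  makePhantomCohort(4, dir, k = 2, seed = 31, shape = c(32, 32, 16))
  cfg <- trainConfig(iterations = 60, evalEvery = 60, seed = 12,
                     patchSize = c(16, 16, 8),
                     network = networkConfig(baseWidth = 2, nStages = 2,
                                             kernelByStage = c(3, 3)))
  r1 <- trainUNet(cfg, dir, fold = 1)
  r2 <- trainUNet(cfg, dir, fold = 1)
  expect_identical(r1$history$loss, r2$history$loss)
  expect_identical(r1$evals, r2$evals)
  expect_identical(r1$model$params, r2$model$params)
  expect_lt(mean(tail(r1$history$loss, 15)),
            mean(head(r1$history$loss, 15)))
  # checkpoint bookkeeping follows validation DSCagg
  expect_identical(r1$bestEval$score, max(r1$evals$mean))
  expect_error(trainUNet(cfg, dir, fold = 99), "no validation patients")
})

test_that("a prior-guided (4-channel) model trains end to end", {
  set.seed(41)
  pairs <- lapply(1:3, function(i)
    generatePairedPhantom(shape = c(16, 16, 8), seed = 40 + i))
  cohort <- lapply(seq_along(pairs), function(i) {
    st <- task2Inputs(pairs[[i]]$mid$volume, pairs[[i]]$pre$volume,
                      pairs[[i]]$pre$mask)
    list(patient = sprintf("P%d", i), fold = if (i == 3) 1 else 2,
         image = st, volume = pairs[[i]]$mid$volume,
         mask = pairs[[i]]$mid$mask)
  })
  cfg <- trainConfig(taskMode = "task2", iterations = 30, evalEvery = 30,
                     seed = 2, patchSize = c(16, 16, 8),
                     network = networkConfig(inChannels = 4, baseWidth = 2,
                                             nStages = 2,
                                             kernelByStage = c(3, 3)))
  res <- trainUNet(cfg, cohort, fold = 1)
  expect_identical(nrow(res$history), 30L)
  expect_true(all(is.finite(res$history$loss)))
  expect_true(is.finite(res$bestEval$score))
})

test_that("YAML round-trips a training configuration", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "iterations: 120",
    "batchSize: 2",
    "patchSize: [16, 16, 8]",
    "normalization: image",
    "pStart: 0.1",
    "pEnd: 0.2",
    "network:",
    "  baseWidth: 4",
    "  nStages: 3",
    "  kernelByStage: [3, 3, 1]",
    "augment:",
    "  rotationMaxDeg: 10"), f)
  cfg <- readTrainConfig(f)
  expect_identical(cfg$iterations, 120L)
  expect_identical(cfg$patchSize, c(16L, 16L, 8L))
  expect_identical(cfg$normalization, "image")
  expect_identical(cfg$network@baseWidth, 4L)
  expect_identical(cfg$network@kernelByStage, c(3L, 3L, 1L))
  expect_equal(cfg$augment$rotationMaxDeg, 10)
})
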