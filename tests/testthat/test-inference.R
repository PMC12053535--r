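test_that("gaussian weight map hits its anchors at center, face and corner", {
  w <- weightValues(gaussianWeightMap(c(21, 21, 9)))
  expect_identical(w[11, 11, 5], 1)
  expect_equal(w[1, 11, 5], 0.1, tolerance = 1e-12)
  expect_equal(w[11, 1, 5], 0.1, tolerance = 1e-12)
  expect_equal(w[11, 11, 1], 0.1, tolerance = 1e-12)
  expect_equal(w[1, 1, 1], 1e-3, tolerance = 1e-9)
  # separable and symmetric per axis
  expect_equal(w[1, , ], w[21, , ])
  expect_true(all(w > 0))
  # single-voxel axes carry weight 1
  expect_true(all(weightValues(gaussianWeightMap(c(1, 5, 1))) <= 1))
  expect_error(gaussianWeightMap(c(5, 5, 5), edgeValue = 0), "edgeValue")
})

test_that("uniform weight map is all ones and matches plain averaging", {
  w <- uniformWeightMap(c(8, 8, 4))
  expect_true(all(weightValues(w) == 1))
  # with uniform weights the blended output is the simple mean of the
  # covering patches: check via a location-dependent function predictor
  counterEnv <- new.env(); counterEnv$i <- 0
  pred <- function(patch) {
    counterEnv$i <- counterEnv$i + 1
    p1 <- array(1 / (1 + counterEnv$i), dim(patch)[1:3])
    array(c(p1, 1 - p1), c(dim(patch)[1:3], 2))
  }
  v <- array(0, c(12, 12, 4))
  out <- slidingWindowPredict(v, pred, patchSize = c(8, 8, 4),
                              stride = c(4, 4, 4), wmap = w,
                              normalize = "none")
  # overlap column covered by windows 1 and 2 equals their mean
  expect_equal(out[6, 2, 2, 1], mean(c(1 / 2, 1 / 3)), tolerance = 1e-12)
})

test_that("a constant-probability model blends to the same constant", {
  const <- c(0.2, 0.5, 0.3)
  pred <- function(patch) {
    d <- dim(patch)[1:3]
    array(rep(const, each = prod(d)), c(d, 3))
  }
  v <- array(rnorm(20 * 20 * 8), c(20, 20, 8))
  for (wm in list(gaussianWeightMap(c(8, 8, 4)), uniformWeightMap(c(8, 8, 4))))
    for (st in list(c(4, 4, 2), c(3, 5, 3))) {
      out <- slidingWindowPredict(v, pred, patchSize = c(8, 8, 4),
                                  stride = st, wmap = wm)
      expect_lt(max(abs(sweep(out, 4, const))), 1e-12)
    }
})

test_that("sliding-window equals whole-volume inference for voxelwise models", {
  set.seed(3)
  # (a) closure predictor: voxelwise softmax of affine intensity maps,
  # arbitrary strides and both weightings
  vox <- function(patch) {
    x <- patch[, , , 1]
    z <- list(0.5 * x, -0.3 * x + 0.1, 0.2 * x - 0.4)
    m <- pmax(z[[1]], pmax(z[[2]], z[[3]]))
    e <- lapply(z, function(zz) exp(zz - m))
    s <- e[[1]] + e[[2]] + e[[3]]
    array(c(e[[1]] / s, e[[2]] / s, e[[3]] / s), c(dim(x), 3))
  }
  v <- array(rnorm(40 * 40 * 20), c(40, 40, 20))
  whole <- vox(array(v, c(dim(v), 1)))
  for (st in list(c(8, 8, 4), c(7, 5, 3)))
    for (wm in list(gaussianWeightMap(c(16, 16, 8)),
                    uniformWeightMap(c(16, 16, 8)))) {
      sw <- slidingWindowPredict(v, vox, patchSize = c(16, 16, 8),
                                 stride = st, wmap = wm, normalize = "none")
      expect_lt(max(abs(sw - whole)), 1e-5)
    }

  # (b) the real network with all-1x1x1 kernels and frozen normalization
  # statistics, at pooling-aligned strides
  model <- voxelwiseModel()
  vn <- normalizePatch(v)
  model <- freezeNormStats(model, array(vn, c(dim(v), 1)))
  whole2 <- predictUNet(model, vn)
  for (st in list(c(8, 8, 4), c(4, 2, 2), c(16, 16, 8))) {
    sw <- slidingWindowPredict(vn, model, patchSize = c(16, 16, 8),
                               stride = st, normalize = "none")
    expect_lt(max(abs(sw - whole2)), 1e-5)
  }
})

test_that("window grid covers every voxel; weighting only touches overlaps", {
  # independent enumeration of the flush-last-window grid
  starts <- function(D, P, S) {
    s <- seq(0, D - P, by = S)
    if (s[length(s)] != D - P) s <- c(s, D - P)
    s
  }
  D <- c(48, 48, 24); P <- c(32, 32, 16); S <- c(8, 8, 4)
  cov <- array(0L, D)
  for (sz in starts(D[3], P[3], S[3]))
    for (sy in starts(D[2], P[2], S[2]))
      for (sx in starts(D[1], P[1], S[1]))
        cov[sx + 1:P[1], sy + 1:P[2], sz + 1:P[3]] <-
          cov[sx + 1:P[1], sy + 1:P[2], sz + 1:P[3]] + 1L
  expect_true(all(cov >= 1L))
  expect_identical(max(cov), 27L)  # 3 starts per axis all overlap centrally

  # gaussian and uniform blending agree exactly when windows do not overlap
  model <- buildUNet(microConfig(), seed = 8)
  v <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  g <- slidingWindowPredict(v, model, patchSize = c(8, 8, 4),
                            stride = c(8, 8, 4))
  u <- slidingWindowPredict(v, model, patchSize = c(8, 8, 4),
                            stride = c(8, 8, 4),
                            wmap = uniformWeightMap(c(8, 8, 4)))
  expect_equal(g, u, tolerance = 1e-12)
  expect_error(slidingWindowPredict(v, model, patchSize = c(8, 8, 4),
                                    stride = c(16, 8, 4)),
               "stride")
})

test_that("labelsFromProbs takes the argmax with ties toward background", {
  p <- array(0, c(2, 2, 1, 3))
  p[1, 1, 1, ] <- c(1, 0, 0)
  p[2, 1, 1, ] <- c(0.2, 0.5, 0.3)
  p[1, 2, 1, ] <- c(1, 1, 1) / 3         # tie: background wins
  p[2, 2, 1, ] <- c(0.1, 0.2, 0.7)
  lab <- maskLabels(labelsFromProbs(p))
  expect_identical(lab[1, 1, 1], 0L)
  expect_identical(lab[2, 1, 1], 1L)
  expect_identical(lab[1, 2, 1], 0L)
  expect_identical(lab[2, 2, 1], 2L)
})

test_that("ensembling reduces correctly and averages probabilities", {
  set.seed(9)
  m1 <- buildUNet(microConfig(), seed = 1)
  ph <- generatePhantom(shape = c(16, 16, 8), seed = 4)
  args <- list(patchSize = c(8, 8, 4), stride = c(4, 4, 2))
  single <- do.call(slidingWindowPredict, c(list(ph$volume, m1), args))
  labSingle <- labelsFromProbs(single, spacing = voxelSpacing(ph$volume))
  # ensemble of one and of identical copies both equal the single model
  e1 <- do.call(ensemblePredict, c(list(ph$volume, list(m1)), args))
  e3 <- do.call(ensemblePredict, c(list(ph$volume, list(m1, m1, m1)), args))
  expect_identical(maskLabels(e1), maskLabels(labSingle))
  expect_identical(maskLabels(e3), maskLabels(labSingle))
  # two voxelwise predictors averaging to a known label
  pA <- function(patch) { d <- dim(patch)[1:3]
    array(rep(c(0.6, 0.4, 0), each = prod(d)), c(d, 3)) }
  pB <- function(patch) { d <- dim(patch)[1:3]
    array(rep(c(0.2, 0.8, 0), each = prod(d)), c(d, 3)) }
  accA <- do.call(slidingWindowPredict, c(list(ph$volume, pA), args))
  accB <- do.call(slidingWindowPredict, c(list(ph$volume, pB), args))
  lab <- labelsFromProbs((accA + accB) / 2)
  expect_true(all(maskLabels(lab) == 1L))  # mean (0.4, 0.6, 0) -> GTVp
  # mismatched signatures are rejected
  m4 <- buildUNet(networkConfig(inChannels = 4, baseWidth = 2, nStages = 2,
                                kernelByStage = c(1, 1)), seed = 2)
  expect_error(ensemblePredict(ph$volume, list(m1, m4)), "signature")
})
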