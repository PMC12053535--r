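test_that("parameter totals match closed-form layer-by-layer accounting", {
  # micro net, counted by hand: 2 stages, base width 2, 1 -> 3 channels,
  # 3x3x3 kernels, 2 blocks/stage. Per conv block: k^3*cin*cout weights +
  # cout bias + 2*cout instance-norm affine.
  cfg <- networkConfig(inChannels = 1, outClasses = 3, baseWidth = 2,
                       nStages = 2, kernelByStage = c(3, 3))
  hand <- (27 * 1 * 2 + 2 + 4) +   # enc1.b1
          (27 * 2 * 2 + 2 + 4) +   # enc1.b2
          (27 * 2 * 4 + 4 + 8) +   # enc2.b1
          (27 * 4 * 4 + 4 + 8) +   # enc2.b2
          (4 * 2 + 2 + 4) +        # dec1 1x1x1 projection block
          (27 * 4 * 2 + 2 + 4) +   # dec1.b1 (concat doubles input)
          (27 * 2 * 2 + 2 + 4) +   # dec1.b2
          (2 * 3 + 3)              # softmax head
  expect_identical(countParameters(cfg), hand)
  # counting a built model agrees with counting its config
  expect_identical(countParameters(buildUNet(cfg, seed = 1)),
                   countParameters(cfg))
})

test_that("parameter count grows monotonically in width and kernel size", {
  base <- networkConfig(baseWidth = 8, nStages = 4,
                        kernelByStage = c(3, 3, 1, 1))
  wider <- networkConfig(baseWidth = 16, nStages = 4,
                         kernelByStage = c(3, 3, 1, 1))
  bigger <- networkConfig(baseWidth = 8, nStages = 4,
                          kernelByStage = c(3, 3, 3, 1))
  expect_gt(countParameters(wider), countParameters(base))
  expect_gt(countParameters(bigger), countParameters(base))
})

test_that("forward pass outputs a probability simplex and is deterministic", {
  model <- buildUNet(microConfig(), seed = 5)
  set.seed(6)
  patch <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  p1 <- predictUNet(model, patch)
  expect_identical(dim(p1), c(8L, 8L, 4L, 3L))
  sums <- apply(p1, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # same input, same weights: identical outputs
  expect_identical(p1, predictUNet(model, patch))
})

test_that("spatial dims not divisible by the pooling factor are rejected", {
  model <- buildUNet(microConfig(), seed = 1)
  expect_error(predictUNet(model, array(0, c(7, 8, 4))), "divisible")
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(42)
  cfg <- networkConfig(inChannels = 2, outClasses = 3, baseWidth = 2,
                       nStages = 2, kernelByStage = c(3, 3))
  model <- buildUNet(cfg, seed = 7)
  sh <- c(4, 4, 2); n <- prod(sh)
  X <- matrix(rnorm(2 * n), n, 2)
  Y <- GTVseg:::.oneHot(sample(0:2, n, TRUE), 3)
  lossFn <- function(m)
    GTVseg:::.diceLossGrad(list(Y),
                           list(GTVseg:::.unetForward(m, X, sh)$probs))$loss
  fw <- GTVseg:::.unetForward(model, X, sh, train = TRUE)
  lg <- GTVseg:::.diceLossGrad(list(Y), list(fw$probs))
  dZ <- fw$probs * (lg$grads[[1]] - rowSums(lg$grads[[1]] * fw$probs))
  ge <- new.env(parent = emptyenv())
  GTVseg:::.unetBackward(model, fw$tape, dZ, ge)
  eps <- 1e-6
  for (nm in names(model$params)) {
    p0 <- model$params[[nm]]
    for (i in sample(length(p0), min(2, length(p0)))) {
      m2 <- model; m2$params[[nm]][i] <- p0[i] + eps
      m3 <- model; m3$params[[nm]][i] <- p0[i] - eps
      num <- (lossFn(m2) - lossFn(m3)) / (2 * eps)
      expect_lt(abs(num - ge[[nm]][i]), 1e-5)
    }
  }
})

test_that("a tiny network overfits a single labeled patch", {
  ph <- generatePhantom(shape = c(24, 24, 12), nGTVp = 1, nGTVn = 0,
                        noiseSd = 0.02, biasAmplitude = 0.1, seed = 31)
  cohort <- list(list(patient = "A", fold = 2, volume = ph$volume,
                      mask = ph$mask),
                 list(patient = "B", fold = 1, volume = ph$volume,
                      mask = ph$mask))
  cfg <- trainConfig(iterations = 200, evalEvery = 200, seed = 3,
                     lrStart = 5e-3, patchSize = c(24, 24, 12),
                     fgFraction = 1, pStart = 0, pEnd = 0, block = 200,
                     network = networkConfig(baseWidth = 4, nStages = 2,
                                             kernelByStage = c(3, 3)))
  res <- trainUNet(cfg, cohort, fold = 1)
  expect_lt(tail(res$history$loss, 1), 0.1)
})
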