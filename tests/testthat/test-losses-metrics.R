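test_that("dsc matches hand-computed overlap cases", {
  y <- c(rep(1, 4), rep(0, 6))
  p <- c(1, 1, 1, 0, 1, 1, 1, 0, 0, 0)   # |y|=4, |p|=6, overlap 3
  expect_equal(dsc(y, p), 0.6, tolerance = 1e-12)
  expect_identical(dsc(y, y), 1)
  # empty truth, non-empty prediction: 0; empty-empty: the convention
  expect_identical(dsc(rep(0, 5), c(1, 0, 0, 0, 0)), 0)
  expect_identical(dsc(rep(0, 5), rep(0, 5)), 1)
  expect_identical(dsc(rep(0, 5), rep(0, 5), emptyEmpty = 0), 0)
  # symmetry
  expect_equal(dsc(y, p), dsc(p, y))
  expect_error(dsc(c(1, 0), c(1, 0, 0)), "shape mismatch")
  expect_error(dsc(c(1, 2), c(1, 0)), "binary")
})

test_that("dscAgg pools sums over pairs and reduces to dsc at N = 1", {
  # perfect 10-voxel match plus an empty-truth pair with 2 false positives
  truths <- list(rep(1, 10), rep(0, 5))
  preds <- list(rep(1, 10), c(1, 1, 0, 0, 0))
  expect_equal(dscAgg(truths, preds), 20 / 22, tolerance = 1e-12)
  # all perfect matches
  expect_identical(dscAgg(list(rep(1, 3), rep(1, 7)),
                          list(rep(1, 3), rep(1, 7))), 1)
  # single non-empty pair equals plain dsc
  set.seed(20)
  y <- rbinom(50, 1, 0.3); p <- rbinom(50, 1, 0.3)
  expect_equal(dscAgg(list(y), list(p)), dsc(y, p), tolerance = 1e-12)
  # symmetry under swapping truth and prediction
  expect_equal(dscAgg(truths, preds), dscAgg(preds, truths))
  # all-empty set falls back to the convention
  expect_identical(dscAgg(list(rep(0, 4)), list(rep(0, 4))), 1)
})

test_that("diceLoss masks absent classes and is zero for perfect predictions", {
  n <- 64
  lab <- sample(0:2, n, replace = TRUE)
  Y <- GTVseg:::.oneHot(lab, 3)
  expect_lt(diceLoss(Y, Y), 1e-6)

  # hand case: one foreground class, |y| = 8 on a 4x4x4 patch, uniform 0.5
  n <- 64
  y <- c(rep(1, 8), rep(0, n - 8))
  Y2 <- cbind(1 - y, y)                 # background + one target class
  P2 <- matrix(0.5, n, 2)
  # target term: 1 - 2*(8*0.5)/(8 + 32) = 0.8
  # background term: 1 - 2*(56*0.5)/(56 + 32) = 1 - 56/88
  expected <- mean(c(1 - 56 / 88, 0.8))
  expect_equal(diceLoss(Y2, P2), expected, tolerance = 1e-6)

  # a class absent from the truth contributes nothing
  lab3 <- sample(c(0, 2), n, replace = TRUE)   # GTVp (class 1) absent
  Y3 <- GTVseg:::.oneHot(lab3, 3)
  P3 <- matrix(runif(3 * n), n, 3); P3 <- P3 / rowSums(P3)
  termFor <- function(cl) {
    a <- sum(Y3[, cl] * P3[, cl]); b <- sum(Y3[, cl]) + sum(P3[, cl])
    1 - 2 * a / (b + 1e-7)
  }
  expect_equal(diceLoss(Y3, P3), mean(c(termFor(1), termFor(3))),
               tolerance = 1e-9)
})

test_that("diceLoss on binary single-class batches equals 1 - dscAgg", {
  set.seed(21)
  # two examples, one foreground class, strictly binary predictions
  y1 <- rbinom(40, 1, 0.4); y2 <- rbinom(40, 1, 0.3)
  p1 <- rbinom(40, 1, 0.4); p2 <- rbinom(40, 1, 0.3)
  truths <- list(cbind(y1), cbind(y2))   # single-class batch (no background)
  probs <- list(cbind(p1), cbind(p2))
  expect_equal(diceLoss(truths, probs),
               1 - dscAgg(list(y1, y2), list(p1, p2)),
               tolerance = 1e-6)
})

test_that("cohort evaluation reports per-patient metrics and per-class DSCagg", {
  ph1 <- generatePhantom(shape = c(24, 24, 12), seed = 1)
  ph2 <- generatePhantom(shape = c(24, 24, 12), nGTVp = 0, nGTVn = 0,
                         seed = 2)
  truths <- list(ph1$mask, ph2$mask)
  preds <- list(maskLabels(ph1$mask), maskLabels(ph2$mask))  # perfect
  ev <- evaluateSegmentation(truths, preds, ids = c("a", "b"))
  expect_identical(nrow(ev$perPatient), 4L)
  expect_true(all(ev$perPatient$dsc == 1))
  expect_identical(unname(ev$cohort[["mean"]]), 1)
  # challenge score is the mean over the two target classes
  expect_equal(ev$cohort[["mean"]],
               mean(c(ev$cohort[["GTVp"]], ev$cohort[["GTVn"]])))
})
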