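# Training workbench: configuration, Adam optimization with cosine
# learning-rate decay, the patch-sampling/augmentation/normalization loop,
# periodic sliding-window validation, and best-checkpoint selection by
# validation mean DSCagg over the two target classes.

#' Cosine learning-rate decay
#'
#' \code{lrEnd + (lrStart - lrEnd) * (1 + cos(pi * iteration / total)) / 2}:
#' monotone non-increasing from \code{lrStart} at iteration 0 to
#' \code{lrEnd} at the final iteration. Defaults follow the common recipe of
#' decaying from 1e-3 to 1e-5 over the run.
#'
#' @param iteration current iteration, in \code{[0, total]}.
#' @param total total planned iterations.
#' @param lrStart initial learning rate.
#' @param lrEnd final learning rate (0 < lrEnd <= lrStart).
#' @return The learning rate.
#' @examples
#' cosineLR(0, 100000)       # 1e-3
#' cosineLR(100000, 100000)  # 1e-5
#' @export
cosineLR <- function(iteration, total, lrStart = 1e-3, lrEnd = 1e-5) {
  stopifnot(lrStart >= lrEnd, lrEnd > 0, total >= 1)
  if (any(iteration < 0) || any(iteration > total))
    stop("iteration out of range [0, total]")
  lrEnd + (lrStart - lrEnd) * (1 + cos(pi * iteration / total)) / 2
}

#' Training configuration
#'
#' Bundles every knob of the training loop. The defaults are a desk-scale
#' recipe (small patches, narrow network); the full-scale recipe used for
#' whole-scan segmentation (patch 320 x 320 x 64, base width 32, batch
#' size 2, 100K iterations, working spacing 0.5 x 0.5 x 2 mm) is available
#' by overriding these fields.
#'
#' @param taskMode \code{"task1"} (single image channel) or \code{"task2"}
#'   (4 channels: mid scan, registered pre scan, two binary prior masks).
#' @param iterations number of training batches.
#' @param batchSize examples per batch.
#' @param lrStart,lrEnd cosine learning-rate bounds.
#' @param evalEvery iterations between validation passes.
#' @param seed master seed for the whole run.
#' @param patchSize training patch extent.
#' @param fgFraction fraction of patches forced to contain a target class.
#' @param normalization \code{"patch"}, \code{"image"} or \code{"none"}.
#' @param pStart,pEnd,block augmentation schedule, see
#'   \code{\link{scheduleProbability}}; set \code{pStart = pEnd} for a
#'   constant-probability policy.
#' @param augment transform parameters, see \code{\link{augmentConfig}}.
#' @param network a \code{\linkS4class{NetworkConfig}}.
#' @param inferenceStride sliding-window stride used for validation.
#' @param weighting \code{"gaussian"} or \code{"uniform"} validation
#'   blending.
#' @param edgeValue Gaussian weight at the patch face centers.
#' @return A named list of class \code{trainConfig}.
#' @export
trainConfig <- function(taskMode = c("task1", "task2"), iterations = 500,
                        batchSize = 2, lrStart = 1e-3, lrEnd = 1e-5,
                        evalEvery = 250, seed = 1,
                        patchSize = c(32, 32, 16), fgFraction = 0.9,
                        normalization = c("patch", "image", "none"),
                        pStart = 0.05, pEnd = 0.25, block = 1000,
                        augment = augmentConfig(),
                        network = networkConfig(baseWidth = 6, nStages = 3,
                                                kernelByStage = c(3, 3, 3)),
                        inferenceStride = patchSize %/% 2,
                        weighting = c("gaussian", "uniform"),
                        edgeValue = 0.1) {
  structure(list(taskMode = match.arg(taskMode), iterations = iterations,
                 batchSize = batchSize, lrStart = lrStart, lrEnd = lrEnd,
                 evalEvery = evalEvery, seed = seed,
                 patchSize = as.integer(patchSize), fgFraction = fgFraction,
                 normalization = match.arg(normalization), pStart = pStart,
                 pEnd = pEnd, block = block, augment = augment,
                 network = network,
                 inferenceStride = as.integer(inferenceStride),
                 weighting = match.arg(weighting), edgeValue = edgeValue),
            class = "trainConfig")
}

#' Read a training configuration from YAML
#'
#' Flat keys mirror the \code{\link{trainConfig}} arguments; the nested
#' \code{network:} block maps to \code{\link{networkConfig}} arguments and
#' \code{augment:} to \code{\link{augmentConfig}}.
#'
#' @param path YAML file path.
#' @return A \code{trainConfig}.
#' @export
readTrainConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("network", "augment"))]
  if (!is.null(y$network)) args$network <- do.call(networkConfig, y$network)
  if (!is.null(y$augment)) args$augment <- do.call(augmentConfig, y$augment)
  do.call(trainConfig, args)
}

#' Stack the four input channels for prior-guided segmentation
#'
#' Builds the 4-channel input of the prior-guided (task 2) mode: the
#' mid-treatment scan, the registered pre-treatment scan, and the two
#' binarized prior masks (GTVp, GTVn) from the pre-treatment annotation.
#' The two image channels are meant to be patch-wise normalized downstream;
#' the two binary mask channels are not. The attached
#' \code{"normalizeChannels"} attribute records exactly that.
#'
#' @param mid \code{\linkS4class{Volume}}, the scan to segment.
#' @param preReg \code{\linkS4class{Volume}}, registered prior scan on the
#'   same grid.
#' @param preMask \code{\linkS4class{LabelMask}} of the prior annotation on
#'   the same grid.
#' @return A 4D array (x, y, z, channel) with attribute
#'   \code{normalizeChannels = c(TRUE, TRUE, FALSE, FALSE)}.
#' @export
task2Inputs <- function(mid, preReg, preMask) {
  stopifnot(is(mid, "Volume"), is(preReg, "Volume"), is(preMask, "LabelMask"))
  d <- dim(mid@data)
  if (!identical(d, dim(preReg@data)) || !identical(d, dim(preMask@labels)))
    stop("grid mismatch: all inputs must share one voxel grid")
  out <- array(0, c(d, 4L))
  out[, , , 1] <- mid@data
  out[, , , 2] <- preReg@data
  out[, , , 3] <- (preMask@labels == 1L) * 1
  out[, , , 4] <- (preMask@labels == 2L) * 1
  attr(out, "normalizeChannels") <- c(TRUE, TRUE, FALSE, FALSE)
  out
}

#' Load a phantom cohort directory
#'
#' Reads the images, masks and fold assignments written by
#' \code{\link{makePhantomCohort}}.
#'
#' @param dir cohort directory.
#' @return A list of examples, each with \code{patient}, \code{fold},
#'   \code{volume} and \code{mask}.
#' @export
loadCohort <- function(dir) {
  folds <- utils::read.csv(file.path(dir, "folds.csv"),
                           stringsAsFactors = FALSE)
  if (nrow(folds) == 0) stop("empty cohort")
  lapply(seq_len(nrow(folds)), function(i) {
    id <- folds$patient_id[i]
    list(patient = id, fold = folds$fold[i],
         volume = readVolume(file.path(dir, "images", paste0(id, ".nii.gz"))),
         mask = readLabelMask(file.path(dir, "masks",
                                        paste0(id, ".nii.gz"))))
  })
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, gradEnv, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- gradEnv[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

.oneHot <- function(labVec, C) {
  out <- matrix(0, length(labVec), C)
  out[cbind(seq_along(labVec), labVec + 1L)] <- 1
  out
}

# assemble one training example: sample spec, extract, augment, normalize;
# returns list(X = (n x C) matrix, Y = one-hot matrix)
.makeTrainingExample <- function(ex, cfg, pAug) {
  spec <- samplePatchSpec(ex$mask, size = cfg$patchSize,
                          targetFraction = cfg$fgFraction)
  normCh <- attr(ex$image, "normalizeChannels")
  d <- dim(ex$image)
  if (length(d) == 3L) {
    imgPatch <- extractPatch(ex$image, spec)
    nCh <- 1L
  } else {
    nCh <- d[4]
    imgPatch <- array(0, c(cfg$patchSize, nCh))
    for (c in seq_len(nCh))
      imgPatch[, , , c] <- extractPatch(ex$image[, , , c], spec)
  }
  maskPatch <- extractPatch(ex$mask, spec)
  # augmentation operates on single-channel patches; stacked prior-guided
  # inputs train unaugmented
  if (pAug > 0 && nCh == 1L) {
    aug <- applyAugmentations(imgPatch, maskPatch, pAug, cfg$augment)
    imgPatch <- aug$patch; maskPatch <- aug$mask
  }
  if (is.null(normCh)) normCh <- rep(TRUE, nCh)
  if (cfg$normalization == "patch") {
    if (nCh == 1L) imgPatch <- normalizePatch(imgPatch)
    else imgPatch <- .normalizeStackPatch(imgPatch, normCh)
  }
  n <- prod(cfg$patchSize)
  list(X = matrix(as.numeric(imgPatch), n, nCh),
       Y = .oneHot(as.vector(maskPatch), cfg$network@outClasses))
}

#' Train the U-Net on a cohort
#'
#' Desk-scale training loop: at every iteration a batch of patches is drawn
#' with the configured target-class bias, augmented at the scheduled
#' probability, normalized, and passed through the network; the
#' present-class batch Dice loss is backpropagated and parameters updated
#' with Adam at the cosine-decayed learning rate. Every \code{evalEvery}
#' iterations the validation patients are segmented by sliding-window
#' inference and per-class DSCagg is logged; the checkpoint with the best
#' validation mean DSCagg over (GTVp, GTVn) is retained. The entire run is
#' reproducible from (config, seed); validation images are never touched by
#' the sampling loop.
#'
#' @param cfg a \code{\link{trainConfig}}.
#' @param cohort either a cohort directory (see
#'   \code{\link{makePhantomCohort}}) or the list returned by
#'   \code{\link{loadCohort}}; for \code{taskMode = "task2"} each example's
#'   \code{image} may be a 4-channel stack from \code{\link{task2Inputs}}.
#' @param fold validation fold number; all other folds train.
#' @param verbose print progress lines.
#' @return A list with \code{model} (best checkpoint), \code{finalModel},
#'   \code{history} (per-iteration loss), \code{evals} (per-validation
#'   DSCagg log) and \code{bestEval}.
#' @export
trainUNet <- function(cfg, cohort, fold = 1, verbose = FALSE) {
  stopifnot(inherits(cfg, "trainConfig"))
  if (is.character(cohort)) cohort <- loadCohort(cohort)
  if (length(cohort) == 0) stop("empty cohort")
  examples <- lapply(cohort, function(ex) {
    img <- if (!is.null(ex$image)) ex$image else ex$volume@data
    list(patient = ex$patient, fold = ex$fold, image = img, mask = ex$mask,
         spacing = if (!is.null(ex$volume)) ex$volume@spacing else c(1, 1, 1))
  })
  isVal <- vapply(examples, function(e) isTRUE(e$fold == fold), logical(1))
  if (!any(isVal)) stop("fold with no validation patients")
  trainEx <- examples[!isVal]; valEx <- examples[isVal]
  if (length(trainEx) == 0) stop("no training patients left")
  set.seed(cfg$seed)
  model <- buildUNet(cfg$network)
  adam <- .adamInit(model$params)
  wmap <- switch(cfg$weighting,
                 gaussian = gaussianWeightMap(cfg$patchSize, cfg$edgeValue),
                 uniform = uniformWeightMap(cfg$patchSize))
  lossLog <- numeric(cfg$iterations)
  evals <- list()
  best <- list(score = -Inf, params = NULL, iteration = NA_integer_)
  for (it in seq_len(cfg$iterations) - 1L) {
    pAug <- scheduleProbability(it, cfg$iterations, cfg$pStart, cfg$pEnd,
                                min(cfg$block, cfg$iterations))
    batch <- lapply(seq_len(cfg$batchSize), function(b) {
      ex <- trainEx[[sample.int(length(trainEx), 1L)]]
      .makeTrainingExample(ex, cfg, pAug)
    })
    fw <- lapply(batch, function(ex)
      .unetForward(model, ex$X, cfg$patchSize, train = TRUE))
    lg <- .diceLossGrad(lapply(batch, `[[`, "Y"),
                        lapply(fw, `[[`, "probs"))
    lossLog[it + 1L] <- lg$loss
    ge <- new.env(parent = emptyenv())
    for (b in seq_along(batch)) {
      P <- fw[[b]]$probs
      dP <- lg$grads[[b]]
      dZ <- P * (dP - rowSums(dP * P))
      .unetBackward(model, fw[[b]]$tape, dZ, ge)
    }
    upd <- .adamStep(model$params, ge, adam,
                     cosineLR(it, cfg$iterations, cfg$lrStart, cfg$lrEnd))
    model$params <- upd$params; adam <- upd$state
    if ((it + 1L) %% cfg$evalEvery == 0L || it + 1L == cfg$iterations) {
      ev <- .validate(model, valEx, cfg, wmap)
      evals[[length(evals) + 1L]] <-
        data.frame(iteration = it + 1L, GTVp = ev[["GTVp"]],
                   GTVn = ev[["GTVn"]], mean = ev[["mean"]])
      if (ev[["mean"]] > best$score)
        best <- list(score = ev[["mean"]], params = model$params,
                     iteration = it + 1L)
      if (verbose)
        message(sprintf("iter %d: loss %.4f, val DSCagg %.3f",
                        it + 1L, lg$loss, ev[["mean"]]))
    }
  }
  bestModel <- model
  if (!is.null(best$params)) bestModel$params <- best$params
  list(model = bestModel, finalModel = model,
       history = data.frame(iteration = seq_len(cfg$iterations),
                            loss = lossLog),
       evals = do.call(rbind, evals),
       bestEval = best[c("score", "iteration")])
}

.validate <- function(model, valEx, cfg, wmap) {
  truths <- list(); preds <- list()
  for (ex in valEx) {
    normCh <- attr(ex$image, "normalizeChannels")
    probs <- slidingWindowPredict(ex$image, model,
                                  patchSize = cfg$patchSize,
                                  stride = cfg$inferenceStride, wmap = wmap,
                                  normalize = cfg$normalization,
                                  normalizeChannels = normCh)
    preds[[length(preds) + 1L]] <- labelsFromProbs(probs)@labels
    truths[[length(truths) + 1L]] <- ex$mask@labels
  }
  dscAggPerClass(truths, preds)
}
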