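# Sliding-window inference: a whole volume is predicted as overlapping
# fixed-size patches whose per-voxel probabilities are blended by a weight
# map. Patch-wise normalization is applied inside the window loop (after
# extraction, before the model call), mirroring how training patches are
# normalized, so inference inputs follow the training input distribution.

#' Gaussian sliding-window weight map
#'
#' Separable product of per-axis Gaussian profiles
#' \code{exp(-d^2 / (2 * sigma_a^2))}, each equal to 1 at the axis center.
#' \code{sigma_a} is set in closed form so the profile equals
#' \code{edgeValue} at the boundary voxel of the axis:
#' \code{sigma_a = ((L_a - 1) / 2) / sqrt(2 * log(1 / edgeValue))}, with
#' distances measured between voxel centers and the axis center at
#' \code{(L_a - 1) / 2}. Consequently the map is 1 at the patch center,
#' exactly \code{edgeValue} at each face center, and \code{edgeValue^3} at
#' the corners. Voxels near the patch center, where patch-based predictions
#' are most reliable, therefore dominate the blend in overlap regions.
#'
#' @param size patch extent in voxels (length 3).
#' @param edgeValue weight at a face-center boundary voxel, in (0, 1];
#'   default 0.1.
#' @return A \code{\linkS4class{WeightMap}}.
#' @examples
#' w <- gaussianWeightMap(c(5, 5, 3))
#' weightValues(w)[3, 3, 2]  # 1 at the center
#' weightValues(w)[1, 3, 2]  # 0.1 at a face center
#' @export
gaussianWeightMap <- function(size, edgeValue = 0.1) {
  size <- as.integer(size)
  stopifnot(length(size) == 3L, all(size >= 1L))
  if (edgeValue <= 0 || edgeValue > 1)
    stop("edgeValue must be in (0, 1]")
  profile <- function(L) {
    if (L == 1L || edgeValue == 1) return(rep(1, L))
    ctr <- (L - 1) / 2
    sigma <- ctr / sqrt(2 * log(1 / edgeValue))
    d <- (seq_len(L) - 1) - ctr
    g <- exp(-d^2 / (2 * sigma^2))
    # for even L no voxel sits at the continuous center; renormalize so the
    # maximal voxel weight is exactly 1 (a no-op for odd L)
    g / max(g)
  }
  w <- outer(outer(profile(size[1]), profile(size[2])), profile(size[3]))
  new("WeightMap", weights = array(w, size))
}

#' Uniform sliding-window weight map
#'
#' All weights equal to 1: blended output is the plain average of the
#' overlapping patch predictions (the equal-weighting baseline).
#'
#' @param size patch extent in voxels (length 3).
#' @return A \code{\linkS4class{WeightMap}}.
#' @export
uniformWeightMap <- function(size) {
  size <- as.integer(size)
  stopifnot(length(size) == 3L, all(size >= 1L))
  new("WeightMap", weights = array(1, size))
}

# window start positions (0-based) covering [0, dimLen) with the final
# window shifted inward to end flush with the volume edge
.windowStarts <- function(dimLen, patchLen, strideLen) {
  if (patchLen >= dimLen) return(0L)
  s <- seq.int(0L, dimLen - patchLen, by = strideLen)
  if (s[length(s)] != dimLen - patchLen) s <- c(s, dimLen - patchLen)
  as.integer(s)
}

.normalizeStackPatch <- function(patch, channelFlags) {
  d <- dim(patch)
  if (length(d) == 3L) return(normalizePatch(patch))
  for (c in seq_len(d[4]))
    if (channelFlags[c])
      patch[, , , c] <- normalizePatch(patch[, , , c])
  patch
}

#' Sliding-window prediction of a whole volume
#'
#' Tiles the volume with patches of \code{patchSize} at steps of
#' \code{stride} (final window per axis shifted inward to end flush with the
#' volume edge, so every voxel is covered at least once), runs the model on
#' each patch and blends the per-patch class probabilities with the weight
#' map: output at a voxel is \code{sum_i w_i p_i / sum_i w_i} over the
#' patches covering it. Because the weights cancel in that ratio, the output
#' is a probability simplex at every voxel, and voxels covered by exactly
#' one patch are unaffected by the choice of weight map.
#'
#' @param v a \code{\linkS4class{Volume}}, or a plain 3D array, or a 4D
#'   array with input channels last (e.g. from \code{\link{task2Inputs}}).
#' @param model a \code{UNet}, or a function taking a 4D patch array
#'   (x, y, z, channel) and returning a 4D (x, y, z, class) probability
#'   array, for custom or reference predictors.
#' @param patchSize patch extent (length 3); defaults to 320 x 320 x 64.
#' @param stride window step per axis, \code{<= patchSize}; defaults to a
#'   quarter of the patch per axis.
#' @param wmap a \code{\linkS4class{WeightMap}} of extent \code{patchSize};
#'   default Gaussian with edge value 0.1.
#' @param normalize \code{"patch"} (z-score each patch after extraction,
#'   the default), \code{"image"} (z-score the whole volume once before
#'   tiling) or \code{"none"}.
#' @param normalizeChannels logical per input channel, for stacked inputs
#'   whose prior-mask channels must pass through unnormalized; default: all
#'   image channels.
#' @return A 4D array (x, y, z, class) of blended probabilities.
#' @export
slidingWindowPredict <- function(v, model, patchSize = c(320, 320, 64),
                                 stride = patchSize %/% 4,
                                 wmap = gaussianWeightMap(patchSize),
                                 normalize = c("patch", "image", "none"),
                                 normalizeChannels = NULL) {
  normalize <- match.arg(normalize)
  arr <- if (is(v, "Volume")) v@data else v
  d <- dim(arr)
  if (length(d) == 3L) { arr <- array(arr, c(d, 1L)); d <- dim(arr) }
  nCh <- d[4]
  if (is.null(normalizeChannels)) normalizeChannels <- rep(TRUE, nCh)
  patchSize <- as.integer(patchSize); stride <- as.integer(stride)
  if (any(stride > patchSize))
    stop("stride must be <= patchSize per axis (coverage gaps otherwise)")
  if (!identical(dim(wmap@weights), patchSize))
    stop("weight map extent must equal patchSize")
  if (normalize == "image")
    arr <- .normalizeStackPatch(arr, normalizeChannels)
  # pad volumes smaller than the patch, crop back at the end
  spat <- d[1:3]
  pad <- pmax(0L, patchSize - spat)
  left <- pad %/% 2L
  if (any(pad > 0L)) {
    padded <- array(0, c(spat + pad, nCh))
    padded[left[1] + seq_len(spat[1]), left[2] + seq_len(spat[2]),
           left[3] + seq_len(spat[3]), ] <- arr
    arr <- padded
  }
  pd <- dim(arr)[1:3]
  predFn <- if (is.function(model)) model else
    function(p) predictUNet(model, p)
  probSum <- NULL
  wSum <- array(0, pd)
  wv <- as.vector(wmap@weights)
  starts <- lapply(1:3, function(a) .windowStarts(pd[a], patchSize[a],
                                                  stride[a]))
  for (sz in starts[[3]]) for (sy in starts[[2]]) for (sx in starts[[1]]) {
    rx <- sx + seq_len(patchSize[1]); ry <- sy + seq_len(patchSize[2])
    rz <- sz + seq_len(patchSize[3])
    patch <- arr[rx, ry, rz, , drop = FALSE]
    dim(patch) <- c(patchSize, nCh)
    if (normalize == "patch")
      patch <- .normalizeStackPatch(patch, normalizeChannels)
    probs <- predFn(patch)
    if (is.null(probSum)) {
      C <- dim(probs)[4]
      probSum <- array(0, c(pd, C))
    }
    probSum[rx, ry, rz, ] <- probSum[rx, ry, rz, ] + as.vector(probs) * wv
    wSum[rx, ry, rz] <- wSum[rx, ry, rz] + wmap@weights
  }
  out <- probSum / as.vector(wSum)
  if (any(pad > 0L))
    out <- out[left[1] + seq_len(spat[1]), left[2] + seq_len(spat[2]),
               left[3] + seq_len(spat[3]), , drop = FALSE]
  array(out, c(spat, C))
}

#' Convert class probabilities to a label mask
#'
#' Voxel-wise argmax over the class axis, with ties broken toward the lowest
#' class index (background).
#'
#' @param p 4D probability array (x, y, z, class).
#' @param spacing voxel spacing for the resulting mask.
#' @param originMeta optional source-grid record to attach.
#' @return A \code{\linkS4class{LabelMask}} with labels in 0..(classes - 1).
#' @export
labelsFromProbs <- function(p, spacing = c(1, 1, 1), originMeta = NULL) {
  d <- dim(p)
  stopifnot(length(d) == 4L)
  m <- matrix(p, prod(d[1:3]), d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  LabelMask(array(lab, d[1:3]), spacing = spacing, originMeta = originMeta)
}

#' Ensemble prediction over several models
#'
#' Averages the sliding-window softmax outputs of all models voxel-wise,
#' applies the argmax, and restores the result to the volume's original
#' grid. An ensemble of one model (or of identical copies) reduces exactly
#' to the single-model prediction.
#'
#' @param v a \code{\linkS4class{Volume}} (or array as in
#'   \code{\link{slidingWindowPredict}}).
#' @param models list of \code{UNet} models with identical configurations.
#' @param ... passed to \code{\link{slidingWindowPredict}}.
#' @return A \code{\linkS4class{LabelMask}} on the volume's original grid
#'   (when origin metadata is available) or its current grid otherwise.
#' @export
ensemblePredict <- function(v, models, ...) {
  stopifnot(length(models) >= 1)
  cfg0 <- models[[1]]$cfg
  for (m in models)
    if (m$cfg@inChannels != cfg0@inChannels ||
        m$cfg@outClasses != cfg0@outClasses)
      stop("all ensemble members must share input/output signatures")
  acc <- NULL
  for (m in models) {
    p <- slidingWindowPredict(v, m, ...)
    acc <- if (is.null(acc)) p else acc + p
  }
  acc <- acc / length(models)
  spacing <- if (is(v, "Volume")) v@spacing else c(1, 1, 1)
  om <- if (is(v, "Volume")) v@originMeta else NULL
  mask <- labelsFromProbs(acc, spacing = spacing, originMeta = om)
  if (length(mask@originMeta) && !is.null(mask@originMeta$shape))
    restoreToOrigin(mask) else mask
}
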