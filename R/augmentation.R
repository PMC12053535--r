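# Training-time data augmentation: six transforms fired independently with a
# shared probability that grows linearly over the course of training.
#
# The schedule intentionally back-loads augmentation: early training sees
# mostly clean patches (fast convergence), late training sees progressively
# more perturbed ones, when overfitting is the dominant risk.

#' Scheduled augmentation probability
#'
#' Per-transform firing probability at a given training iteration. The
#' probability is piecewise-constant within blocks of \code{block} batches
#' and increases linearly from \code{pStart} in the first block to exactly
#' \code{pEnd} in the last block:
#' \code{p = pStart + (pEnd - pStart) * k / (K - 1)} with
#' \code{k = iteration \%/\% block} and \code{K = totalIterations \%/\% block}.
#' The defaults (0.05 to 0.25, adjusted every 1000 batches) give 0.05
#' throughout the first 1K batches of a run and 0.25 throughout the last.
#'
#' @param iteration 0-based batch counter, in \code{[0, totalIterations)}.
#' @param totalIterations planned number of batches (>= block).
#' @param pStart initial probability.
#' @param pEnd final probability (>= pStart).
#' @param block adjustment granularity in batches.
#' @return Probability in \code{[pStart, pEnd]}, non-decreasing in
#'   \code{iteration}.
#' @examples
#' scheduleProbability(0, 100000)      # 0.05
#' scheduleProbability(99999, 100000)  # 0.25
#' @export
scheduleProbability <- function(iteration, totalIterations,
                                pStart = 0.05, pEnd = 0.25, block = 1000) {
  stopifnot(pStart >= 0, pStart <= pEnd, pEnd <= 1, block >= 1,
            totalIterations >= block)
  if (any(iteration < 0) || any(iteration >= totalIterations))
    stop("iteration out of range [0, totalIterations)")
  K <- totalIterations %/% block
  if (K == 1L) return(rep(pStart, length(iteration)))
  k <- pmin(iteration %/% block, K - 1)
  pStart + (pEnd - pStart) * k / (K - 1)
}

#' Augmentation configuration
#'
#' Enable flags and parameter ranges for the six transforms. Ranges are
#' conventional for T2w MRI: in-plane rotations within +/- 15 degrees
#' (rotating only in-plane respects the strongly anisotropic voxels),
#' gamma contrast in [0.8, 1.25], a smooth multiplicative bias field with
#' relative amplitude up to 0.3, ghosting-style motion imitation along one
#' axis, and additive Gaussian noise with sd up to 0.1 of the patch sd.
#'
#' @param mirror,rotation,contrast,biasField,motion,noise logical enable flags.
#' @param mirrorAxes axes eligible for mirroring (subset of 1:3).
#' @param rotationMaxDeg maximum in-plane rotation angle, degrees.
#' @param gammaRange length-2 range for the contrast gamma exponent.
#' @param biasAmplitude maximum relative amplitude of the bias field.
#' @param motionMaxShift maximum ghosting shift, voxels.
#' @param motionMaxWeight maximum ghost blend weight.
#' @param noiseMaxSd maximum additive noise sd, as a fraction of the patch sd.
#' @return A named list consumed by \code{\link{applyAugmentations}}.
#' @export
augmentConfig <- function(mirror = TRUE, rotation = TRUE, contrast = TRUE,
                          biasField = TRUE, motion = TRUE, noise = TRUE,
                          mirrorAxes = c(1L, 2L, 3L), rotationMaxDeg = 15,
                          gammaRange = c(0.8, 1.25), biasAmplitude = 0.3,
                          motionMaxShift = 4L, motionMaxWeight = 0.2,
                          noiseMaxSd = 0.1) {
  list(enabled = c(mirror = mirror, rotation = rotation, contrast = contrast,
                   biasField = biasField, motion = motion, noise = noise),
       mirrorAxes = as.integer(mirrorAxes), rotationMaxDeg = rotationMaxDeg,
       gammaRange = gammaRange, biasAmplitude = biasAmplitude,
       motionMaxShift = as.integer(motionMaxShift),
       motionMaxWeight = motionMaxWeight, noiseMaxSd = noiseMaxSd)
}

.flipAxis <- function(arr, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(arr)[axis]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

# in-plane (xy) rotation about the patch center; identical geometry for image
# (bilinear) and mask (nearest-neighbor); voxels mapped from outside -> 0
.rotateInPlane <- function(arr, angleDeg, nearest = FALSE) {
  d <- dim(arr)
  th <- angleDeg * pi / 180
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
  gx <- rep(seq_len(d[1]) - 1, times = d[2]) - cx
  gy <- rep(seq_len(d[2]) - 1, each = d[1]) - cy
  # inverse rotation: source coords for each output voxel
  sx <- cos(th) * gx + sin(th) * gy + cx
  sy <- -sin(th) * gx + cos(th) * gy + cy
  flat <- matrix(arr, d[1] * d[2], d[3])
  out <- matrix(0, d[1] * d[2], d[3])
  inside <- sx >= 0 & sx <= d[1] - 1 & sy >= 0 & sy <= d[2] - 1
  if (nearest) {
    ix <- .roundHalfUp(sx); iy <- .roundHalfUp(sy)
    ok <- inside
    lin <- ix[ok] + 1 + d[1] * iy[ok]
    out[ok, ] <- flat[lin, ]
  } else {
    x0 <- pmin(pmax(floor(sx), 0), d[1] - 1); fx <- sx - x0
    y0 <- pmin(pmax(floor(sy), 0), d[2] - 1); fy <- sy - y0
    x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
    g <- function(ix, iy) flat[ix + 1 + d[1] * iy, , drop = FALSE]
    val <- (1 - fx) * (1 - fy) * g(x0, y0) + fx * (1 - fy) * g(x1, y0) +
           (1 - fx) * fy * g(x0, y1) + fx * fy * g(x1, y1)
    val[!inside, ] <- 0
    out <- val
  }
  array(out, d)
}

.gammaContrast <- function(arr, gamma) {
  lo <- min(arr); r <- max(arr) - lo
  if (r <= 0) return(arr)
  ((arr - lo) / r)^gamma * r + lo
}

# smooth multiplicative field: random quadratic polynomial over normalized
# coordinates, scaled to max |deviation| = amp, so the field lies in 1 +/- amp
.randomBiasField <- function(d, amp) {
  co <- rnorm(9)
  ax <- lapply(d, function(n) if (n > 1) seq(-1, 1, length.out = n) else 0)
  gx <- array(rep(ax[[1]], times = d[2] * d[3]), d)
  gy <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
  gz <- array(rep(ax[[3]], each = d[1] * d[2]), d)
  f <- co[1] * gx + co[2] * gy + co[3] * gz + co[4] * gx * gy +
       co[5] * gx * gz + co[6] * gy * gz + co[7] * gx^2 + co[8] * gy^2 +
       co[9] * gz^2
  m <- max(abs(f))
  if (m > 0) f <- f / m
  1 + amp * f
}

.shiftAxis <- function(arr, axis, shift) {
  n <- dim(arr)[axis]
  idx <- ((seq_len(n) - 1 - shift) %% n) + 1
  sel <- rep(list(quote(expr = )), 3)
  sel[[axis]] <- idx
  do.call(`[`, c(list(arr), sel, list(drop = FALSE)))
}

#' Apply the six training augmentations
#'
#' Each transform fires independently with probability \code{p}: mirroring
#' and in-plane rotation are spatial and applied identically to the image
#' patch and its mask (mask via nearest-neighbor, so the label set can never
#' grow); gamma contrast, multiplicative bias field, motion (ghosting)
#' imitation and additive Gaussian noise touch the image only. With
#' \code{p = 0} the inputs are returned bit-identical. Intended to run
#' before \code{\link{normalizePatch}} so the perturbed statistics are
#' re-standardized.
#'
#' @param patch numeric 3D image patch.
#' @param maskPatch integer 3D label patch, congruent with \code{patch}.
#' @param p per-transform firing probability in [0, 1], typically from
#'   \code{\link{scheduleProbability}}.
#' @param config transform parameters, see \code{\link{augmentConfig}}.
#' @param seed optional integer for a locally reproducible draw.
#' @return A list with elements \code{patch}, \code{mask} and \code{fired}
#'   (named logical vector of which transforms were applied).
#' @export
applyAugmentations <- function(patch, maskPatch, p, config = augmentConfig(),
                               seed = NULL) {
  stopifnot(identical(dim(patch), dim(maskPatch)), p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  fired <- runif(6) < p & config$enabled
  names(fired) <- names(config$enabled)
  if (fired["mirror"]) {
    ax <- config$mirrorAxes[sample.int(length(config$mirrorAxes), 1L)]
    patch <- .flipAxis(patch, ax)
    maskPatch <- .flipAxis(maskPatch, ax)
  }
  if (fired["rotation"]) {
    ang <- runif(1, -config$rotationMaxDeg, config$rotationMaxDeg)
    patch <- .rotateInPlane(patch, ang, nearest = FALSE)
    maskPatch <- .rotateInPlane(maskPatch, ang, nearest = TRUE)
    storage.mode(maskPatch) <- "integer"
  }
  if (fired["contrast"])
    patch <- .gammaContrast(patch, runif(1, config$gammaRange[1],
                                         config$gammaRange[2]))
  if (fired["biasField"])
    patch <- patch * .randomBiasField(dim(patch),
                                      runif(1, 0, config$biasAmplitude))
  if (fired["motion"]) {
    ax <- sample.int(3L, 1L)
    shift <- sample.int(config$motionMaxShift, 1L)
    w <- runif(1, 0, config$motionMaxWeight)
    patch <- (1 - w) * patch +
      (w / 2) * (.shiftAxis(patch, ax, shift) + .shiftAxis(patch, ax, -shift))
  }
  if (fired["noise"]) {
    sdv <- sqrt(mean((patch - mean(patch))^2))
    noiseSd <- runif(1, 0, config$noiseMaxSd) * sdv
    patch <- patch + array(rnorm(length(patch), sd = noiseSd), dim(patch))
  }
  list(patch = patch, mask = maskPatch, fired = fired)
}
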