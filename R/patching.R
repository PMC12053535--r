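# Patch sampling, extraction and z-score intensity normalization.
#
# MRI intensities are not on a standardized scale: global shift/scale and
# smooth bias fields differ between scans. Normalizing each patch after
# extraction (rather than the whole image before it) makes every model input
# exactly zero-mean/unit-variance wherever it came from, which removes the
# location- and scan-dependent covariate shift that image-wise normalization
# leaves behind.

# symmetric zero-padding of a 3D array up to at least `size` per axis;
# returns the padded array and the left offsets applied
.padToSize <- function(arr, size, value = 0) {
  d <- dim(arr)
  pad <- pmax(0L, as.integer(size) - d)
  if (all(pad == 0L)) return(list(arr = arr, offset = c(0L, 0L, 0L)))
  left <- pad %/% 2L
  out <- array(value, d + pad)
  storage.mode(out) <- storage.mode(arr)
  out[left[1] + seq_len(d[1]), left[2] + seq_len(d[2]),
      left[3] + seq_len(d[3])] <- arr
  list(arr = out, offset = left)
}

#' Sample a patch location with target-class bias
#'
#' Draws the position of one training patch. With probability
#' \code{targetFraction} the patch is forced to contain at least one voxel
#' labeled GTVp or GTVn (when the mask has any): a target voxel is picked
#' uniformly at random and the patch start is then uniform among all starts
#' whose patch covers that voxel. Otherwise, and always when the mask has no
#' target voxels, the start is uniform over all valid positions. The default
#' \code{targetFraction} of 0.9 gives the 90/10 mix of target-containing and
#' fully random training patches.
#'
#' Volumes smaller than the patch are implicitly zero-padded symmetrically
#' (as in \code{\link{extractPatch}}); returned starts refer to the padded
#' grid.
#'
#' @param mask a \code{\linkS4class{LabelMask}} at the working spacing.
#' @param size patch extent in voxels (length 3); default 320 x 320 x 64.
#' @param targetFraction probability in [0, 1] of forcing target coverage.
#' @param seed optional integer; when given, the draw is made reproducible by
#'   seeding R's RNG locally.
#' @return A \code{\linkS4class{PatchSpec}} (0-based start).
#' @export
samplePatchSpec <- function(mask, size = c(320, 320, 64),
                            targetFraction = 0.9, seed = NULL) {
  stopifnot(is(mask, "LabelMask"))
  if (targetFraction < 0 || targetFraction > 1)
    stop("targetFraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  size <- as.integer(size)
  d <- dim(mask@labels)
  padded <- pmax(d, size)
  offset <- pmax(0L, size - d) %/% 2L
  maxStart <- padded - size  # inclusive upper bound, 0-based
  forced <- runif(1) < targetFraction
  targetIdx <- which(mask@labels > 0L)
  if (forced && length(targetIdx)) {
    v <- targetIdx[sample.int(length(targetIdx), 1L)] - 1L
    vx <- c(v %% d[1], (v %/% d[1]) %% d[2], v %/% (d[1] * d[2])) + offset
    lo <- pmax(0L, vx - size + 1L)
    hi <- pmin(maxStart, vx)
    start <- lo + vapply(hi - lo + 1L,
                         function(n) sample.int(n, 1L) - 1L, integer(1))
  } else {
    start <- vapply(maxStart + 1L,
                    function(n) sample.int(n, 1L) - 1L, integer(1))
  }
  PatchSpec(start = start, size = size)
}

#' Extract a patch from a volume or mask
#'
#' Returns the sub-array of exactly \code{spec@size} voxels starting at the
#' 0-based corner \code{spec@start}. Inputs smaller than the patch along any
#' axis are zero-padded symmetrically before extraction; \code{spec} then
#' addresses the padded grid.
#'
#' @param x a \code{\linkS4class{Volume}}, \code{\linkS4class{LabelMask}} or
#'   plain 3D array.
#' @param spec a \code{\linkS4class{PatchSpec}} valid for the (padded) grid.
#' @return A plain 3D array of extent \code{spec@size} (integer for masks).
#' @export
extractPatch <- function(x, spec) {
  arr <- if (is(x, "Volume")) x@data else if (is(x, "LabelMask")) x@labels else x
  stopifnot(length(dim(arr)) == 3L, is(spec, "PatchSpec"))
  p <- .padToSize(arr, spec@size)
  d <- dim(p$arr)
  if (any(spec@start + spec@size > d))
    stop("patch spec out of bounds for (padded) volume")
  p$arr[spec@start[1] + seq_len(spec@size[1]),
        spec@start[2] + seq_len(spec@size[2]),
        spec@start[3] + seq_len(spec@size[3]), drop = FALSE]
}

#' Patch-wise z-score normalization
#'
#' Shifts and scales a patch to zero mean and unit standard deviation
#' (population convention, divide by N). A constant patch, e.g. one lying in
#' zero-padding, returns all zeros rather than dividing by zero. Applied
#' after patch extraction this guarantees identical first- and second-order
#' input statistics for every patch regardless of the global intensity scale
#' of the scan it came from: \code{normalizePatch(a * x + b)} equals
#' \code{normalizePatch(x)} for any a > 0.
#'
#' @param patch numeric array (any shape, non-empty).
#' @return Array of the same shape with mean 0 and sd 1 (or all zeros).
#' @export
normalizePatch <- function(patch) {
  stopifnot(length(patch) > 0)
  mu <- mean(patch)
  sdv <- sqrt(mean((patch - mu)^2))
  if (sdv <= 0 || !is.finite(sdv)) {
    patch[] <- 0
    return(patch)
  }
  (patch - mu) / sdv
}

#' Image-wise z-score normalization (baseline mode)
#'
#' Normalizes the whole volume once, before any patch extraction. This is
#' the conventional baseline: patches cut from an image-wise-normalized
#' volume have means and variances that depend on where they were cut,
#' unlike \code{\link{normalizePatch}} which forces them to (0, 1).
#' Provided so the two normalization modes can be compared.
#'
#' @param v a \code{\linkS4class{Volume}}.
#' @return A \code{\linkS4class{Volume}} with globally normalized intensities.
#' @export
normalizeVolume <- function(v) {
  stopifnot(is(v, "Volume"))
  new("Volume", data = normalizePatch(v@data), spacing = v@spacing,
      originMeta = v@originMeta)
}
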