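# NIfTI I/O and grid resampling.
#
# Coordinate convention used across the package: 0-based voxel indices, axis
# order (x, y, z) matching the header spacing order. Voxel i sits at physical
# position i * spacing along its axis. All images are reoriented to the RAS
# canonical orientation on read; originMeta records the source orientation so
# writes can restore it.

.gtvError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gtvsegError", "error", "condition")))
}

.captureOrigin <- function(img) {
  list(shape = dim(img)[1:3],
       spacing = as.numeric(RNifti::pixdim(img))[1:3],
       orientation = RNifti::orientation(img),
       header = RNifti::niftiHeader(img))
}

.readNiftiCanonical <- function(path) {
  if (!file.exists(path))
    .gtvError(sprintf("missing file: %s", path), "gtvMissingFileError")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    .gtvError(sprintf("unreadable NIfTI header: %s (%s)",
                                      path, conditionMessage(e)),
                              "gtvHeaderError"))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    # degenerate singleton 4th axis is tolerated and dropped
    img <- RNifti::asNifti(array(as.array(img), d[1:3]), reference = img)
    d <- dim(img)
  }
  if (length(d) != 3L)
    .gtvError(sprintf("non-3D image: %s has %d axes", path, length(d)),
              "gtvNon3DImageError")
  meta <- .captureOrigin(img)
  if (RNifti::niftiHeader(img)$qform_code > 0 ||
      RNifti::niftiHeader(img)$sform_code > 0)
    RNifti::orientation(img) <- "RAS"
  dat <- array(as.vector(img), dim(img))  # strip niftiImage attributes
  list(data = dat, spacing = as.numeric(RNifti::pixdim(img))[1:3],
       originMeta = meta)
}

#' Read a 3D NIfTI volume
#'
#' Reads a scalar image, reorients it to the RAS canonical orientation and
#' records the source grid (shape, spacing, orientation, header) in
#' \code{originMeta} for later restoration. Intensities are converted to
#' double precision regardless of the on-disk dtype.
#'
#' @param path path to a \code{.nii} / \code{.nii.gz} file holding a 3D image.
#' @return A \code{\linkS4class{Volume}}.
#' @export
readVolume <- function(path) {
  r <- .readNiftiCanonical(path)
  storage.mode(r$data) <- "double"
  new("Volume", data = r$data, spacing = r$spacing, originMeta = r$originMeta)
}

#' Read a 3D NIfTI label mask
#'
#' As \code{\link{readVolume}} but values are validated against the
#' three-class label set \{0 = background, 1 = GTVp, 2 = GTVn\}.
#'
#' @inheritParams readVolume
#' @return A \code{\linkS4class{LabelMask}}.
#' @export
readLabelMask <- function(path) {
  r <- .readNiftiCanonical(path)
  lab <- round(r$data)
  storage.mode(lab) <- "integer"
  new("LabelMask", labels = lab, spacing = r$spacing, originMeta = r$originMeta)
}

.writeNiftiWithMeta <- function(arr, spacing, originMeta, path, datatype) {
  # RAS-aligned diagonal xform so the file carries a well-defined orientation
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- 0
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  orient <- if (length(originMeta)) originMeta$orientation else "RAS"
  if (!identical(orient, "RAS"))
    RNifti::orientation(img) <- orient
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a Volume to NIfTI
#'
#' Intensities are stored as 32-bit floating point. If the volume carries a
#' source orientation in \code{originMeta} it is restored on write.
#'
#' @param v a \code{\linkS4class{Volume}}.
#' @param path output \code{.nii} / \code{.nii.gz} path.
#' @return the path, invisibly.
#' @export
writeVolume <- function(v, path) {
  stopifnot(is(v, "Volume"))
  .writeNiftiWithMeta(v@data, v@spacing, v@originMeta, path, "float")
}

#' Write a LabelMask to NIfTI
#'
#' Masks are stored as unsigned 8-bit integers.
#'
#' @param m a \code{\linkS4class{LabelMask}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeLabelMask <- function(m, path) {
  stopifnot(is(m, "LabelMask"))
  .writeNiftiWithMeta(m@labels, m@spacing, m@originMeta, path, "uint8")
}

# round half away from zero (base round() is banker's)
.roundHalfUp <- function(x) floor(x + 0.5)

# Resample a 3D array from inSpacing to targetSpacing.
# method: "linear" (trilinear) or "nearest".
# outShape overrides the shape rule (used for exact origin restoration).
.resampleArray <- function(arr, inSpacing, targetSpacing, method,
                           outShape = NULL) {
  inShape <- dim(arr)
  if (is.null(outShape))
    outShape <- pmax(1, .roundHalfUp(inShape * inSpacing / targetSpacing))
  outShape <- as.integer(outShape)
  # source coordinate (0-based, continuous) of each output voxel per axis
  src <- lapply(1:3, function(a) {
    pos <- (seq_len(outShape[a]) - 1) * targetSpacing[a] / inSpacing[a]
    pmin(pmax(pos, 0), inShape[a] - 1)
  })
  if (method == "nearest") {
    idx <- lapply(1:3, function(a) as.integer(.roundHalfUp(src[[a]])) + 1L)
    return(array(arr[idx[[1]], idx[[2]], idx[[3]]], outShape))
  }
  i0 <- lapply(1:3, function(a) pmin(floor(src[[a]]), inShape[a] - 1))
  fr <- lapply(1:3, function(a) src[[a]] - i0[[a]])
  i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1, inShape[a] - 1))
  nx <- inShape[1]; nxy <- inShape[1] * inShape[2]
  out <- array(0, outShape)
  for (c3 in 0:1) for (c2 in 0:1) for (c1 in 0:1) {
    wx <- if (c1) fr[[1]] else 1 - fr[[1]]
    wy <- if (c2) fr[[2]] else 1 - fr[[2]]
    wz <- if (c3) fr[[3]] else 1 - fr[[3]]
    if (all(wx == 0) || all(wy == 0) || all(wz == 0)) next
    ix <- if (c1) i1[[1]] else i0[[1]]
    iy <- if (c2) i1[[2]] else i0[[2]]
    iz <- if (c3) i1[[3]] else i0[[3]]
    lin <- outer(outer(ix + 1, iy * nx, "+"), iz * nxy, "+")
    w <- outer(outer(wx, wy), wz)
    out <- out + w * array(arr[lin], outShape)
  }
  out
}

#' Resample to a target voxel spacing
#'
#' Volumes are resampled with trilinear interpolation, label masks with
#' nearest-neighbor interpolation (so the label set can never grow). The
#' output shape per axis is \code{round(shape * spacing / target)} with ties
#' away from zero and a minimum of 1. \code{originMeta} is carried over
#' unchanged from the source, so \code{\link{restoreToOrigin}} can always get
#' back to the grid the image was read on.
#'
#' @param x a \code{\linkS4class{Volume}} or \code{\linkS4class{LabelMask}}.
#' @param targetSpacing numeric length-3, target mm per axis; all components
#'   strictly positive.
#' @return An object of the same class as \code{x} on the new grid.
#' @examples
#' v <- Volume(array(rnorm(64 * 64 * 32), c(64, 64, 32)), spacing = c(1, 1, 2))
#' dim(resampleToSpacing(v, c(0.5, 0.5, 2)))  # 128 128 32
#' @export
setGeneric("resampleToSpacing",
           function(x, targetSpacing) standardGeneric("resampleToSpacing"))

#' @rdname resampleToSpacing
setMethod("resampleToSpacing", "Volume", function(x, targetSpacing) {
  targetSpacing <- as.numeric(targetSpacing)
  if (length(targetSpacing) != 3L || any(targetSpacing <= 0))
    .gtvError("target spacing must be 3 strictly positive values",
              "gtvSpacingError")
  new("Volume",
      data = .resampleArray(x@data, x@spacing, targetSpacing, "linear"),
      spacing = targetSpacing, originMeta = x@originMeta)
})

#' @rdname resampleToSpacing
setMethod("resampleToSpacing", "LabelMask", function(x, targetSpacing) {
  targetSpacing <- as.numeric(targetSpacing)
  if (length(targetSpacing) != 3L || any(targetSpacing <= 0))
    .gtvError("target spacing must be 3 strictly positive values",
              "gtvSpacingError")
  lab <- .resampleArray(x@labels, x@spacing, targetSpacing, "nearest")
  storage.mode(lab) <- "integer"
  new("LabelMask", labels = lab, spacing = targetSpacing,
      originMeta = x@originMeta)
})

#' Restore a mask to its source grid
#'
#' Resamples a label mask back to the exact shape and spacing recorded in its
#' \code{originMeta} (the grid of the file it was read from), using
#' nearest-neighbor interpolation only. A mask already on its original grid
#' is returned unchanged.
#'
#' @param m a \code{\linkS4class{LabelMask}} with populated \code{originMeta}.
#' @return A \code{\linkS4class{LabelMask}} on the original grid.
#' @export
restoreToOrigin <- function(m) {
  stopifnot(is(m, "LabelMask"))
  om <- m@originMeta
  if (!length(om) || is.null(om$shape) || is.null(om$spacing))
    .gtvError("missing originMeta: cannot restore", "gtvMissingOriginError")
  if (identical(dim(m@labels), as.integer(om$shape)) &&
      isTRUE(all.equal(m@spacing, om$spacing)))
    return(m)
  lab <- .resampleArray(m@labels, m@spacing, om$spacing, "nearest",
                        outShape = om$shape)
  storage.mode(lab) <- "integer"
  new("LabelMask", labels = lab, spacing = as.numeric(om$spacing),
      originMeta = om)
}
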