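#' @import methods
#' @importFrom stats rnorm runif sd
NULL

#' Volume: a 3D scalar image with voxel spacing
#'
#' Container for a single three-dimensional scalar image (typically a
#' T2-weighted MRI scan). Voxel indices are 0-based in the public API and the
#' axis order is (x, y, z), matching the order of the \code{spacing} vector.
#' Intensities are held as double precision but are converted from 32-bit
#' storage on read, so arbitrary on-disk dtypes are accepted.
#'
#' The \code{originMeta} slot is an opaque record of the source grid (shape,
#' spacing, orientation and NIfTI header) captured at read time. It travels
#' unchanged through resampling so that predictions computed on a working
#' grid can be restored exactly to the source grid with
#' \code{\link{restoreToOrigin}}.
#'
#' @slot data numeric 3D array of intensities.
#' @slot spacing numeric length-3 vector, voxel size in mm per axis.
#' @slot originMeta list describing the source grid, or an empty list for
#'   volumes created in memory.
#'
#' @seealso \code{\link{readVolume}}, \code{\link{resampleToSpacing}}
#' @export
setClass("Volume",
  representation(data = "array", spacing = "numeric", originMeta = "list"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            originMeta = list()))

#' LabelMask: a 3D integer segmentation mask
#'
#' Companion class to \code{\linkS4class{Volume}} holding the segmentation
#' labels: 0 = background, 1 = primary gross tumor volume (GTVp),
#' 2 = metastatic lymph nodes (GTVn). Labels are always integral; every
#' spatial operation on a mask uses nearest-neighbor interpolation so no
#' fractional values can ever appear.
#'
#' @slot labels integer-valued 3D array with values in \{0, 1, 2\}.
#' @slot spacing numeric length-3 vector, mm per axis.
#' @slot originMeta list, as in \code{\linkS4class{Volume}}.
#'
#' @export
setClass("LabelMask",
  representation(labels = "array", spacing = "numeric", originMeta = "list"),
  prototype(labels = array(0L, c(1, 1, 1)), spacing = c(1, 1, 1),
            originMeta = list()))

#' PatchSpec: location and size of one patch
#'
#' @slot start integer length-3 vector, 0-based inclusive voxel index of the
#'   patch corner on the (possibly padded) volume grid.
#' @slot size integer length-3 vector, patch extent in voxels.
#'
#' @seealso \code{\link{samplePatchSpec}}, \code{\link{extractPatch}}
#' @export
setClass("PatchSpec",
  representation(start = "integer", size = "integer"),
  prototype(start = c(0L, 0L, 0L), size = c(320L, 320L, 64L)))

#' NetworkConfig: per-stage configuration of the 3D U-Net
#'
#' Describes the encoder/decoder layout: \code{nStages} resolution stages
#' with channel count \code{baseWidth * 2^(s-1)} at stage s, isotropic
#' convolution kernel edge \code{kernelByStage[s]} for both the encoder and
#' the decoder blocks of that stage, and \code{blocksPerStage} convolutional
#' blocks (conv + instance norm + ReLU) per stage on each path. The default
#' configuration uses 1x1x1 kernels in stages 5-6, which shrinks the
#' parameter total from roughly 86 million (all-3x3x3) to roughly 14 million.
#'
#' @slot inChannels integer, input channels (1 for plain segmentation, 4 when
#'   a registered prior scan plus two binary prior masks are stacked).
#' @slot outClasses integer, output classes (3: background, GTVp, GTVn).
#' @slot baseWidth integer, channels at stage 1.
#' @slot nStages integer, number of resolution stages.
#' @slot kernelByStage integer vector of odd kernel edges, one per stage.
#' @slot blocksPerStage integer, conv blocks per stage.
#'
#' @seealso \code{\link{networkConfig}}, \code{\link{buildUNet}}
#' @export
setClass("NetworkConfig",
  representation(inChannels = "integer", outClasses = "integer",
                 baseWidth = "integer", nStages = "integer",
                 kernelByStage = "integer", blocksPerStage = "integer"))

#' WeightMap: per-voxel blending weights for sliding-window inference
#'
#' @slot weights 3D array of strictly positive weights, maximal (= 1) at the
#'   patch center.
#'
#' @seealso \code{\link{gaussianWeightMap}}, \code{\link{uniformWeightMap}}
#' @export
setClass("WeightMap", representation(weights = "array"))

setValidity("Volume", function(object) {
  if (length(dim(object@data)) != 3L) return("data must have exactly 3 axes")
  if (any(dim(object@data) < 1L)) return("all dims must be >= 1")
  if (length(object@spacing) != 3L) return("spacing must have length 3")
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("spacing components must be strictly positive")
  TRUE
})

setValidity("LabelMask", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must have exactly 3 axes")
  if (length(object@spacing) != 3L) return("spacing must have length 3")
  if (any(object@spacing <= 0)) return("spacing components must be strictly positive")
  vals <- unique(as.vector(object@labels))
  if (any(vals != as.integer(vals)) || !all(vals %in% c(0, 1, 2)))
    return("label values must be integers in {0, 1, 2}")
  TRUE
})

setValidity("PatchSpec", function(object) {
  if (length(object@start) != 3L || length(object@size) != 3L)
    return("start and size must have length 3")
  if (any(object@start < 0L)) return("start must be >= 0 per axis")
  if (any(object@size < 1L)) return("size must be >= 1 per axis")
  TRUE
})

setValidity("NetworkConfig", function(object) {
  if (object@nStages < 2L) return("nStages must be >= 2")
  if (length(object@kernelByStage) != object@nStages)
    return("kernelByStage must have one entry per stage")
  if (any(object@kernelByStage < 1L) || any(object@kernelByStage %% 2L == 0L))
    return("kernel edges must be odd and >= 1")
  if (object@inChannels < 1L || object@outClasses < 2L)
    return("inChannels >= 1 and outClasses >= 2 required")
  if (object@baseWidth < 1L || object@blocksPerStage < 1L)
    return("baseWidth and blocksPerStage must be >= 1")
  TRUE
})

setValidity("WeightMap", function(object) {
  if (length(dim(object@weights)) != 3L) return("weights must be a 3D array")
  if (any(object@weights <= 0)) return("weights must be strictly positive")
  if (abs(max(object@weights) - 1) > 1e-8) return("maximum weight must be 1")
  TRUE
})

# ---- constructors -----------------------------------------------------------

#' Create a Volume from an array
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, mm per axis.
#' @param originMeta optional source-grid record; defaults to the volume's
#'   own grid so a fresh in-memory volume is its own origin.
#' @return A \code{\linkS4class{Volume}}.
#' @export
Volume <- function(data, spacing = c(1, 1, 1), originMeta = NULL) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  if (is.null(originMeta))
    originMeta <- list(shape = dim(data), spacing = as.numeric(spacing),
                       orientation = "RAS", header = NULL)
  new("Volume", data = data, spacing = as.numeric(spacing),
      originMeta = originMeta)
}

#' Create a LabelMask from an array
#'
#' @param labels integer-valued 3D array over \{0, 1, 2\}.
#' @inheritParams Volume
#' @return A \code{\linkS4class{LabelMask}}.
#' @export
LabelMask <- function(labels, spacing = c(1, 1, 1), originMeta = NULL) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (is.null(originMeta))
    originMeta <- list(shape = dim(labels), spacing = as.numeric(spacing),
                       orientation = "RAS", header = NULL)
  new("LabelMask", labels = labels, spacing = as.numeric(spacing),
      originMeta = originMeta)
}

#' Create a PatchSpec
#'
#' @param start 0-based inclusive corner index, length 3.
#' @param size patch extent in voxels, length 3.
#' @return A \code{\linkS4class{PatchSpec}}.
#' @export
PatchSpec <- function(start = c(0, 0, 0), size = c(320, 320, 64)) {
  new("PatchSpec", start = as.integer(start), size = as.integer(size))
}

#' Create a NetworkConfig
#'
#' Defaults reproduce the reduced six-stage layout: base width 32, channel
#' doubling after each 2x2x2 max-pool, 3x3x3 kernels in stages 1-4 and 1x1x1
#' kernels in stages 5-6, two conv blocks per stage.
#'
#' @param inChannels input channels.
#' @param outClasses output classes.
#' @param baseWidth channels at stage 1.
#' @param nStages number of resolution stages.
#' @param kernelByStage odd kernel edge per stage.
#' @param blocksPerStage conv blocks per stage.
#' @return A \code{\linkS4class{NetworkConfig}}.
#' @examples
#' cfg <- networkConfig()
#' countParameters(cfg)  # about 14 million
#' @export
networkConfig <- function(inChannels = 1, outClasses = 3, baseWidth = 32,
                          nStages = 6,
                          kernelByStage = c(3, 3, 3, 3, 1, 1),
                          blocksPerStage = 2) {
  new("NetworkConfig", inChannels = as.integer(inChannels),
      outClasses = as.integer(outClasses), baseWidth = as.integer(baseWidth),
      nStages = as.integer(nStages),
      kernelByStage = as.integer(kernelByStage),
      blocksPerStage = as.integer(blocksPerStage))
}

# ---- accessors --------------------------------------------------------------

#' @describeIn Volume-class the intensity array.
#' @param x a Volume or LabelMask.
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
setMethod("volData", "Volume", function(x) x@data)

#' @describeIn LabelMask-class the integer label array.
#' @param x a LabelMask.
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
setMethod("maskLabels", "LabelMask", function(x) x@labels)

#' Voxel spacing accessor
#' @param x a Volume or LabelMask.
#' @return numeric length-3, mm per axis.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
setMethod("voxelSpacing", "Volume", function(x) x@spacing)
setMethod("voxelSpacing", "LabelMask", function(x) x@spacing)

#' Source-grid metadata accessor
#' @param x a Volume or LabelMask.
#' @return list recording the grid of the image as read from disk.
#' @export
setGeneric("originMeta", function(x) standardGeneric("originMeta"))
setMethod("originMeta", "Volume", function(x) x@originMeta)
setMethod("originMeta", "LabelMask", function(x) x@originMeta)

#' Weight array accessor
#' @param x a WeightMap.
#' @export
setGeneric("weightValues", function(x) standardGeneric("weightValues"))
setMethod("weightValues", "WeightMap", function(x) x@weights)

setMethod("dim", "Volume", function(x) dim(x@data))
setMethod("dim", "LabelMask", function(x) dim(x@labels))
setMethod("dim", "WeightMap", function(x) dim(x@weights))

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume %dx%dx%d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@labels)
  tab <- tabulate(as.vector(object@labels) + 1L, nbins = 3L)
  cat(sprintf("LabelMask %dx%dx%d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  background %d | GTVp %d | GTVn %d voxels\n",
              tab[1], tab[2], tab[3]))
})

setMethod("show", "NetworkConfig", function(object) {
  ch <- object@baseWidth * 2^(seq_len(object@nStages) - 1L)
  cat(sprintf("NetworkConfig: %d stages, %d -> %d channels, kernels [%s]\n",
              object@nStages, object@inChannels, object@outClasses,
              paste(object@kernelByStage, collapse = ",")))
  cat(sprintf("  channels by stage: %s; %d blocks/stage\n",
              paste(ch, collapse = ", "), object@blocksPerStage))
})

setMethod("show", "WeightMap", function(object) {
  d <- dim(object@weights)
  cat(sprintf("WeightMap %dx%dx%d, range [%.4g, 1]\n",
              d[1], d[2], d[3], min(object@weights)))
})
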