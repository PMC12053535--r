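# Shared fixtures: all tiny, generated in code at test time.

tinyVolume <- function(shape = c(8, 8, 4), spacing = c(1, 1, 2), seed = 1) {
  set.seed(seed)
  Volume(array(rnorm(prod(shape), mean = 100, sd = 10), shape),
         spacing = spacing)
}

# mask with one small lesion block per requested class
tinyMask <- function(shape = c(8, 8, 4), spacing = c(1, 1, 2),
                     classes = c(1L, 2L)) {
  lab <- array(0L, shape)
  if (1L %in% classes) lab[2:3, 2:3, 2] <- 1L
  if (2L %in% classes) lab[6:7, 6:7, 3] <- 2L
  LabelMask(lab, spacing = spacing)
}

# a micro network config whose forward pass runs in milliseconds
microConfig <- function(inChannels = 1, baseWidth = 2, nStages = 2,
                        kernels = c(3, 1)) {
  networkConfig(inChannels = inChannels, outClasses = 3,
                baseWidth = baseWidth, nStages = nStages,
                kernelByStage = kernels)
}

# purely voxelwise network: all 1x1x1 kernels so every voxel is processed
# independently of its neighbors (sliding-window oracle)
voxelwiseModel <- function(seed = 42) {
  cfg <- networkConfig(inChannels = 1, outClasses = 3, baseWidth = 4,
                       nStages = 2, kernelByStage = c(1, 1))
  buildUNet(cfg, seed = seed)
}
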