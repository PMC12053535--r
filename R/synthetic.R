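# Synthetic T2w-like phantoms with two lesion classes.
#
# The generator reproduces the properties the segmentation pipeline is built
# to handle: smooth band-limited background anatomy, bright ellipsoidal
# lesions (GTVp brighter than background, GTVn brighter still), a smooth
# multiplicative bias field, a per-image global intensity shift/scale (the
# non-standardized MRI intensity scale), and additive Gaussian noise. It
# makes no claim of anatomical realism: lesions are ellipsoids, anatomy is a
# random field, and no k-space physics is simulated.

# trilinearly upsample a coarse random grid to `shape` (band-limited field)
.smoothField <- function(shape, coarse = c(6, 6, 4)) {
  g <- array(rnorm(prod(coarse)), coarse)
  .resampleArray(g, inSpacing = (shape - 1) / pmax(coarse - 1, 1),
                 targetSpacing = c(1, 1, 1), method = "linear",
                 outShape = shape)
}

.ellipsoidMask <- function(shape, center, radii) {
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - 1) - center[a]) /
                 radii[a])
  outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+") <= 1
}

# draw disjoint ellipsoid lesions; returns list of list(center, radii, class)
# radius ranges shrink automatically so lesions always fit small volumes
.drawLesions <- function(shape, nGTVp, nGTVn, maxTries = 250L) {
  lesions <- list()
  occupied <- array(FALSE, shape)
  fitRange <- function(lo, hi, dims) {
    cap <- (min(dims) - 7) / 2  # radius + 2-voxel margin must fit inside
    hi <- max(min(hi, cap), 0.5)
    c(min(lo, 0.7 * hi), hi)
  }
  place <- function(cl, xy, z) {
    xy <- fitRange(xy[1], xy[2], shape[1:2])
    z <- fitRange(z[1], z[2], shape[3])
    for (t in seq_len(maxTries)) {
      # anneal the radii downward every 25 failed tries so crowded small
      # volumes still place all lesions disjointly
      sc <- 0.8^((t - 1) %/% 25)
      radii <- pmax(c(runif(1, xy[1], xy[2]), runif(1, xy[1], xy[2]),
                      runif(1, z[1], z[2])) * sc, 0.5)
      margin <- pmin(ceiling(radii) + 2, (shape - 1) %/% 2)
      center <- vapply(1:3, function(a)
        runif(1, margin[a], shape[a] - 1 - margin[a]), numeric(1))
      m <- .ellipsoidMask(shape, center, radii)
      if (any(m) && !any(m & occupied)) {
        occupied <<- occupied | m
        return(list(center = center, radii = radii, class = cl, mask = m))
      }
    }
    stop("could not place lesions disjointly after bounded retries")
  }
  for (i in seq_len(nGTVp))
    lesions[[length(lesions) + 1L]] <- place(1L, c(7, 12), c(3.5, 6))
  for (i in seq_len(nGTVn))
    lesions[[length(lesions) + 1L]] <- place(2L, c(3.5, 7), c(2, 4))
  lesions
}

# render an image + mask from anatomy and lesion geometry
.renderPhantom <- function(anatomy, lesions, shrink, spacing,
                           intensityShift, intensityScale, biasAmplitude,
                           noiseSd) {
  shape <- dim(anatomy)
  baseMean <- mean(anatomy)
  img <- anatomy
  lab <- array(0L, shape)
  contrast <- c(0.3, 0.5)  # GTVp +30%, GTVn +50% of background mean
  for (L in lesions) {
    if (shrink <= 0) next
    m <- if (shrink == 1) L$mask else
      .ellipsoidMask(shape, L$center, L$radii * shrink)
    img[m] <- anatomy[m] + contrast[L$class] * baseMean
    lab[m] <- L$class
  }
  bias <- if (biasAmplitude > 0) .randomBiasField(shape, biasAmplitude) else 1
  img <- img * bias
  img <- intensityScale * img + intensityShift
  if (noiseSd > 0)
    img <- img + array(rnorm(prod(shape),
                             sd = noiseSd * baseMean * intensityScale),
                       shape)
  list(volume = Volume(img, spacing = spacing),
       mask = LabelMask(lab, spacing = spacing))
}

#' Generate a synthetic MRI phantom with two lesion classes
#'
#' Builds a smooth random background (mean about 100 intensity units) with
#' disjoint ellipsoidal lesions — GTVp at +30\% and GTVn at +50\% of the
#' background mean — multiplied by a low-frequency bias field, affinely
#' transformed by the global \code{intensityScale}/\code{intensityShift}
#' (emulating the arbitrary MRI intensity scale), and corrupted by additive
#' Gaussian noise. Deterministic for a given \code{seed}.
#'
#' @param shape volume extent in voxels; default 96 x 96 x 48.
#' @param spacing voxel spacing in mm; default (1, 1, 2).
#' @param nGTVp number of primary-tumor lesions (0 or 1).
#' @param nGTVn number of nodal lesions (>= 0).
#' @param intensityShift global additive offset applied after the bias field.
#' @param intensityScale global multiplicative gain (> 0).
#' @param biasAmplitude relative amplitude of the multiplicative bias field.
#' @param noiseSd additive noise sd as a fraction of the background mean.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return A list with elements \code{volume}
#'   (\code{\linkS4class{Volume}}) and \code{mask}
#'   (\code{\linkS4class{LabelMask}}).
#' @export
generatePhantom <- function(shape = c(96, 96, 48), spacing = c(1, 1, 2),
                            nGTVp = 1, nGTVn = 2, intensityShift = 0,
                            intensityScale = 1, biasAmplitude = 0.2,
                            noiseSd = 0.05, seed = NULL) {
  stopifnot(intensityScale > 0, nGTVp %in% c(0, 1), nGTVn >= 0)
  if (!is.null(seed)) set.seed(seed)
  shape <- as.integer(shape)
  anatomy <- 100 * (1 + 0.25 * .smoothField(shape))
  lesions <- .drawLesions(shape, nGTVp, nGTVn)
  .renderPhantom(anatomy, lesions, shrink = 1, spacing, intensityShift,
                 intensityScale, biasAmplitude, noiseSd)
}

#' Generate a registered pre-/mid-treatment phantom pair
#'
#' The pre-treatment pair is generated as in \code{\link{generatePhantom}};
#' the mid-treatment pair shares the same anatomy and voxel grid
#' (pre-registered by construction) but has every lesion shrunk about its
#' center by \code{shrinkFactor} (simulating treatment response; 0 removes
#' all lesions, 1 keeps them identical) and independent bias-field,
#' intensity and noise draws.
#'
#' @inheritParams generatePhantom
#' @param shrinkFactor per-axis lesion shrink factor in [0, 1].
#' @return A list with \code{pre} and \code{mid}, each a
#'   \code{volume}/\code{mask} pair.
#' @export
generatePairedPhantom <- function(shape = c(96, 96, 48), spacing = c(1, 1, 2),
                                  nGTVp = 1, nGTVn = 2, shrinkFactor = 0.5,
                                  intensityShift = 0, intensityScale = 1,
                                  biasAmplitude = 0.2, noiseSd = 0.05,
                                  seed = NULL) {
  stopifnot(shrinkFactor >= 0, shrinkFactor <= 1)
  if (!is.null(seed)) set.seed(seed)
  shape <- as.integer(shape)
  anatomy <- 100 * (1 + 0.25 * .smoothField(shape))
  lesions <- .drawLesions(shape, nGTVp, nGTVn)
  pre <- .renderPhantom(anatomy, lesions, 1, spacing, intensityShift,
                        intensityScale, biasAmplitude, noiseSd)
  mid <- .renderPhantom(anatomy, lesions, shrinkFactor, spacing,
                        intensityShift, intensityScale, biasAmplitude,
                        noiseSd)
  list(pre = pre, mid = mid)
}

#' Patient-wise cross-validation folds
#'
#' Partitions patients into \code{k} near-equal folds (sizes differ by at
#' most one), shuffled deterministically per seed. All images of a patient
#' inherit its single fold assignment, so no patient ever spans the
#' training/validation boundary.
#'
#' @param patientIds character or integer vector of patient identifiers
#'   (repeats allowed: one entry per image is fine).
#' @param k number of folds (>= 2, <= number of distinct patients).
#' @param seed integer seed for the shuffle.
#' @return A data.frame with columns \code{patient_id} and \code{fold}
#'   (one row per distinct patient).
#' @export
makeFolds <- function(patientIds, k = 5, seed = NULL) {
  ids <- unique(as.character(patientIds))
  if (k < 2) stop("k must be >= 2")
  if (length(ids) < k) stop("fewer patients than folds")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(ids)
  fold <- rep_len(seq_len(k), length(perm))
  data.frame(patient_id = perm, fold = fold,
             stringsAsFactors = FALSE)[order(perm), , drop = FALSE]
}

#' Write a phantom cohort to disk
#'
#' Generates \code{n} single-scan phantom patients with per-image global
#' intensity scale and shift drawn at random (scale log-uniform in
#' [0.5, 5], shift uniform in [0, 50]), emulating a cohort acquired on
#' non-standardized scanners, and writes NIfTI images and masks plus a
#' patient-to-fold CSV.
#'
#' @param n number of patients.
#' @param dir output directory (created if needed); images go to
#'   \code{dir/images}, masks to \code{dir/masks}, folds to
#'   \code{dir/folds.csv}.
#' @param k number of cross-validation folds.
#' @param seed integer seed governing the whole cohort.
#' @param ... passed to \code{\link{generatePhantom}} (shape, spacing,
#'   lesion counts, noise, ...).
#' @return The cohort directory, invisibly.
#' @export
makePhantomCohort <- function(n, dir, k = min(5, n), seed = 1, ...) {
  set.seed(seed)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("P%03d", seq_len(n))
  scales <- exp(runif(n, log(0.5), log(5)))
  shifts <- runif(n, 0, 50)
  seeds <- sample.int(1e6, n)
  for (i in seq_len(n)) {
    ph <- generatePhantom(intensityScale = scales[i],
                          intensityShift = shifts[i], seed = seeds[i], ...)
    writeVolume(ph$volume, file.path(dir, "images",
                                     paste0(ids[i], ".nii.gz")))
    writeLabelMask(ph$mask, file.path(dir, "masks",
                                      paste0(ids[i], ".nii.gz")))
  }
  folds <- makeFolds(ids, k = k, seed = seed)
  utils::write.csv(folds, file.path(dir, "folds.csv"), row.names = FALSE)
  invisible(dir)
}
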