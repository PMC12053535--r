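# A 3D U-Net implemented natively in R.
#
# Feature maps are stored as dense matrices of shape (n_voxels, channels)
# with the voxel axis in (x, y, z) column-major order. Convolutions run as
# one BLAS dgemm per kernel offset over a physically zero-padded grid (see
# src/conv3d.cpp); weights for a k x k x k convolution are stored as a
# (k^3 * inChannels) x outChannels matrix with the kernel-offset index
# varying fastest. Encoder stages are
# separated by 2x2x2 max pooling with channel doubling; the decoder halves
# channels with a 1x1x1 conv block, doubles resolution by nearest-neighbor
# interpolation and concatenates the encoder skip at the same stage.
#
# Every conv block is conv -> instance norm (learnable affine) -> ReLU.
# Instance normalization is computed per channel over the spatial axes of
# each example independently.

.idxCacheEnv <- new.env(parent = emptyenv())

# 2x2x2 max-pool gather indices: (n_out x 8) matrix of input row ids
.poolIdx <- function(shape) {
  key <- paste0("p", paste(shape, collapse = "_"))
  hit <- .idxCacheEnv[[key]]
  if (!is.null(hit)) return(hit)
  os <- shape %/% 2L
  n_out <- prod(os)
  ox <- (seq_len(n_out) - 1L) %% os[1]
  oy <- ((seq_len(n_out) - 1L) %/% os[1]) %% os[2]
  oz <- (seq_len(n_out) - 1L) %/% (os[1] * os[2])
  off <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)
  P <- matrix(0L, n_out, 8L)
  for (j in 1:8) {
    P[, j] <- (2L * ox + off$dx[j]) + shape[1] * (2L * oy + off$dy[j]) +
      shape[1] * shape[2] * (2L * oz + off$dz[j]) + 1L
  }
  .idxCacheEnv[[key]] <- P
  P
}

# nearest-neighbor 2x upsampling indices: input row id for each output voxel
.upIdx <- function(shapeIn) {
  key <- paste0("u", paste(shapeIn, collapse = "_"))
  hit <- .idxCacheEnv[[key]]
  if (!is.null(hit)) return(hit)
  os <- shapeIn * 2L
  n_out <- prod(os)
  ox <- (seq_len(n_out) - 1L) %% os[1]
  oy <- ((seq_len(n_out) - 1L) %/% os[1]) %% os[2]
  oz <- (seq_len(n_out) - 1L) %/% (os[1] * os[2])
  U <- (ox %/% 2L) + shapeIn[1] * (oy %/% 2L) +
    shapeIn[1] * shapeIn[2] * (oz %/% 2L) + 1L
  .idxCacheEnv[[key]] <- U
  U
}

.stageWidths <- function(cfg) cfg@baseWidth * 2L^(seq_len(cfg@nStages) - 1L)

# Enumerate every trainable array of the network: name -> c(dims, fanIn).
# Shared by buildUNet() and countParameters() so the two can never diverge.
.layerSpecs <- function(cfg) {
  w <- .stageWidths(cfg)
  S <- cfg@nStages; B <- cfg@blocksPerStage
  specs <- list()
  addBlock <- function(key, cin, cout, k) {
    specs[[paste0(key, ".W")]] <<- list(dim = c(k^3 * cin, cout),
                                        fanIn = k^3 * cin, kind = "W")
    specs[[paste0(key, ".b")]] <<- list(dim = cout, kind = "zero")
    specs[[paste0(key, ".g")]] <<- list(dim = cout, kind = "one")
    specs[[paste0(key, ".be")]] <<- list(dim = cout, kind = "zero")
  }
  for (s in seq_len(S)) {
    k <- cfg@kernelByStage[s]
    for (b in seq_len(B)) {
      cin <- if (b > 1L) w[s] else if (s == 1L) cfg@inChannels else w[s - 1L]
      addBlock(sprintf("enc%d.b%d", s, b), cin, w[s], k)
    }
  }
  for (s in rev(seq_len(S - 1L))) {
    addBlock(sprintf("dec%d.proj", s), w[s + 1L], w[s], 1L)
    k <- cfg@kernelByStage[s]
    for (b in seq_len(B)) {
      cin <- if (b == 1L) 2L * w[s] else w[s]
      addBlock(sprintf("dec%d.b%d", s, b), cin, w[s], k)
    }
  }
  specs[["head.W"]] <- list(dim = c(w[1], cfg@outClasses), fanIn = w[1],
                            kind = "W")
  specs[["head.b"]] <- list(dim = cfg@outClasses, kind = "zero")
  specs
}

#' Build the 3D U-Net
#'
#' Instantiates the network described by a \code{\linkS4class{NetworkConfig}}
#' with He-initialized convolution weights, zero biases and identity
#' instance-norm affine parameters. The returned model is a plain parameter
#' container evaluated by \code{\link{predictUNet}} (inference) and trained
#' by \code{\link{trainUNet}}.
#'
#' @param cfg a \code{\linkS4class{NetworkConfig}}.
#' @param seed optional integer seed for reproducible initialization.
#' @return An object of class \code{UNet}: a list with elements \code{cfg}
#'   and \code{params} (named list of weight arrays).
#' @export
buildUNet <- function(cfg, seed = NULL) {
  stopifnot(is(cfg, "NetworkConfig"))
  validObject(cfg)
  if (!is.null(seed)) set.seed(seed)
  specs <- .layerSpecs(cfg)
  params <- lapply(specs, function(sp) {
    switch(sp$kind,
      W = matrix(rnorm(prod(sp$dim), sd = sqrt(2 / sp$fanIn)),
                 sp$dim[1], sp$dim[2]),
      zero = rep(0, sp$dim),
      one = rep(1, sp$dim))
  })
  structure(list(cfg = cfg, params = params), class = "UNet")
}

#' Count trainable parameters
#'
#' Total number of trainable scalars of the network a config describes:
#' convolution weights and biases plus instance-norm scale and shift. The
#' default configuration (1x1x1 kernels in stages 5-6) totals about 14
#' million; switching those stages to 3x3x3 kernels raises it to about 86
#' million.
#'
#' @param x a \code{\linkS4class{NetworkConfig}} or a built \code{UNet}.
#' @return Integer-valued parameter count.
#' @examples
#' round(countParameters(networkConfig()) / 1e6)                        # 14
#' round(countParameters(networkConfig(kernelByStage = rep(3, 6))) / 1e6) # 86
#' @export
countParameters <- function(x) {
  if (inherits(x, "UNet")) return(sum(vapply(x$params, length, numeric(1))))
  stopifnot(is(x, "NetworkConfig"))
  sum(vapply(.layerSpecs(x), function(sp) prod(sp$dim), numeric(1)))
}

#' @export
print.UNet <- function(x, ...) {
  cat(sprintf("UNet: %s parameters\n",
              format(countParameters(x), big.mark = ",")))
  print(x$cfg)
  invisible(x)
}

# ---- layer primitives (feature matrices: n_vox x channels) ------------------

.convForward <- function(X, W, b, shape, k) {
  Y <- if (k == 1L) X %*% W + rep(b, each = nrow(X))
       else .conv3dFwdCpp(X, W, b, shape, k)
  list(Y = Y, xin = X)
}

# weight permutation for the transposed convolution used in the input
# gradient: [(offset, cin), cout] -> [(reversed offset, cout), cin]
.permWForDx <- function(W, k3, cin, cout) {
  Wa <- array(W, c(k3, cin, cout))
  matrix(aperm(Wa[k3:1, , , drop = FALSE], c(1, 3, 2)), k3 * cout, cin)
}

.convBackward <- function(dY, xin, W, shape, k, cin) {
  db <- colSums(dY)
  if (k == 1L) {
    dW <- crossprod(xin, dY)
    dX <- dY %*% t(W)
  } else {
    dW <- .conv3dDwCpp(xin, dY, shape, k)
    # input gradient is a convolution of dY with the offset-reversed,
    # channel-transposed kernel
    dX <- .conv3dFwdCpp(dY, .permWForDx(W, k^3, cin, ncol(dY)),
                        numeric(cin), shape, k)
  }
  list(dX = dX, dW = dW, db = db)
}

.inEps <- 1e-5

.instNormForward <- function(X, g, be, stats = NULL) {
  n <- nrow(X)
  if (is.null(stats)) {
    mu <- colMeans(X)
    v <- colMeans(X * X) - mu * mu
    invsd <- 1 / sqrt(pmax(v, 0) + .inEps)
  } else {
    mu <- stats$mu
    invsd <- stats$invsd
  }
  xhat <- (X - rep(mu, each = n)) * rep(invsd, each = n)
  list(Y = xhat * rep(g, each = n) + rep(be, each = n),
       xhat = xhat, invsd = invsd, mu = mu)
}

.instNormBackward <- function(dY, xhat, invsd, g) {
  n <- nrow(dY)
  dg <- colSums(dY * xhat)
  dbe <- colSums(dY)
  dxhat <- dY * rep(g, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dX <- rep(invsd / n, each = n) *
    (n * dxhat - rep(s1, each = n) - xhat * rep(s2, each = n))
  list(dX = dX, dg = dg, dbe = dbe)
}

.blockForward <- function(params, key, X, shape, k, train, tape,
                          frozen = NULL, capture = NULL) {
  W <- params[[paste0(key, ".W")]]
  cv <- .convForward(X, W, params[[paste0(key, ".b")]], shape, k)
  inr <- .instNormForward(cv$Y, params[[paste0(key, ".g")]],
                          params[[paste0(key, ".be")]],
                          stats = if (!is.null(frozen)) frozen[[key]])
  if (!is.null(capture))
    capture[[key]] <- list(mu = inr$mu, invsd = inr$invsd)
  Y <- inr$Y
  Y[Y < 0] <- 0
  if (train)
    tape[[length(tape) + 1L]] <- list(type = "block", key = key,
                                      xin = cv$xin, shape = shape, k = k,
                                      cin = ncol(X), xhat = inr$xhat,
                                      invsd = inr$invsd, out = Y)
  list(Y = Y, tape = tape)
}

# accumulate into gradient environment `ge` and return the input gradient
.blockBackward <- function(params, rec, dY, ge) {
  dY <- dY * (rec$out > 0)
  inb <- .instNormBackward(dY, rec$xhat, rec$invsd,
                           params[[paste0(rec$key, ".g")]])
  cb <- .convBackward(inb$dX, rec$xin, params[[paste0(rec$key, ".W")]],
                      rec$shape, rec$k, rec$cin)
  .accumGrad(ge, paste0(rec$key, ".W"), cb$dW)
  .accumGrad(ge, paste0(rec$key, ".b"), cb$db)
  .accumGrad(ge, paste0(rec$key, ".g"), inb$dg)
  .accumGrad(ge, paste0(rec$key, ".be"), inb$dbe)
  cb$dX
}

.accumGrad <- function(ge, name, g) {
  cur <- ge[[name]]
  ge[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

.softmaxRows <- function(Z) {
  mx <- Z[, 1]
  for (c in seq_len(ncol(Z))[-1]) mx <- pmax(mx, Z[, c])
  E <- exp(Z - mx)
  E / rowSums(E)
}

# Forward pass for one example.
# X: (n_vox x inChannels) matrix; shape: spatial dims.
# Returns probs (n_vox x outClasses) and, when train = TRUE, the tape needed
# by .unetBackward.
.unetForward <- function(model, X, shape, train = FALSE, capture = NULL) {
  cfg <- model$cfg; params <- model$params
  frozen <- if (!train) model$frozenStats
  S <- cfg@nStages; B <- cfg@blocksPerStage
  div <- 2L^(S - 1L)
  if (any(shape %% div != 0L))
    stop(sprintf("input spatial dims (%s) must be divisible by %d",
                 paste(shape, collapse = "x"), div))
  tape <- list()
  shapes <- lapply(seq_len(S), function(s) shape %/% 2L^(s - 1L))
  cur <- X; skips <- vector("list", S - 1L)
  for (s in seq_len(S)) {
    k <- cfg@kernelByStage[s]
    for (b in seq_len(B)) {
      r <- .blockForward(params, sprintf("enc%d.b%d", s, b), cur,
                         shapes[[s]], k, train, tape, frozen, capture)
      cur <- r$Y; tape <- r$tape
    }
    if (s < S) {
      skips[[s]] <- cur
      P <- .poolIdx(shapes[[s]])
      nOut <- nrow(P); C <- ncol(cur)
      Yp <- matrix(0, nOut, C)
      sel <- matrix(0L, nOut, C)
      for (c in seq_len(C)) {
        V <- cur[, c][P]
        amax <- max.col(matrix(V, nOut, 8L), ties.method = "first")
        sel[, c] <- P[cbind(seq_len(nOut), amax)]
        Yp[, c] <- cur[sel[, c], c]
      }
      if (train)
        tape[[length(tape) + 1L]] <- list(type = "pool", sel = sel,
                                          nIn = nrow(cur), stage = s)
      cur <- Yp
    }
  }
  for (s in rev(seq_len(S - 1L))) {
    r <- .blockForward(params, sprintf("dec%d.proj", s), cur,
                       shapes[[s + 1L]], 1L, train, tape, frozen, capture)
    cur <- r$Y; tape <- r$tape
    U <- .upIdx(shapes[[s + 1L]])
    if (train)
      tape[[length(tape) + 1L]] <- list(type = "up", U = U, nIn = nrow(cur))
    cur <- cur[U, , drop = FALSE]
    nUp <- ncol(cur)
    cur <- cbind(cur, skips[[s]])
    if (train)
      tape[[length(tape) + 1L]] <- list(type = "concat", nUp = nUp,
                                        stage = s)
    k <- cfg@kernelByStage[s]
    for (b in seq_len(B)) {
      r <- .blockForward(params, sprintf("dec%d.b%d", s, b), cur,
                         shapes[[s]], k, train, tape, frozen, capture)
      cur <- r$Y; tape <- r$tape
    }
  }
  logits <- cur %*% params$head.W + rep(params$head.b, each = nrow(cur))
  if (train)
    tape[[length(tape) + 1L]] <- list(type = "head", cols = cur)
  list(probs = .softmaxRows(logits), tape = tape)
}

# Backward pass for one example; dLogits is the gradient of the loss with
# respect to the pre-softmax logits. Parameter gradients are accumulated
# into the environment `ge` (name -> array), allowing batch pooling.
.unetBackward <- function(model, tape, dLogits, ge) {
  params <- model$params
  rec <- tape[[length(tape)]]
  stopifnot(rec$type == "head")
  .accumGrad(ge, "head.W", crossprod(rec$cols, dLogits))
  .accumGrad(ge, "head.b", colSums(dLogits))
  d <- dLogits %*% t(params$head.W)
  skipGrads <- list()
  for (i in rev(seq_len(length(tape) - 1L))) {
    rec <- tape[[i]]
    if (rec$type == "block") {
      d <- .blockBackward(params, rec, d, ge)
    } else if (rec$type == "concat") {
      # gradient w.r.t. the skip branch parks until its encoder pool
      skipGrads[[rec$stage]] <- d[, -seq_len(rec$nUp), drop = FALSE]
      d <- d[, seq_len(rec$nUp), drop = FALSE]
    } else if (rec$type == "up") {
      d <- rowsum(d, rec$U)
    } else if (rec$type == "pool") {
      dIn <- matrix(0, rec$nIn, ncol(d))
      for (c in seq_len(ncol(d))) dIn[rec$sel[, c], c] <- d[, c]
      d <- dIn + skipGrads[[rec$stage]]
    }
  }
  invisible(NULL)
}

#' Predict class probabilities for one patch
#'
#' Runs the network forward in inference mode on a single patch.
#'
#' @param model a \code{UNet} from \code{\link{buildUNet}}.
#' @param patch numeric array, either 3D (single input channel) or 4D with
#'   the channel axis last; spatial dims must be divisible by
#'   \code{2^(nStages - 1)}.
#' @return A 4D array (x, y, z, class) of softmax probabilities summing to 1
#'   at every voxel.
#' @export
predictUNet <- function(model, patch) {
  d <- dim(patch)
  if (length(d) == 3L) d <- c(d, 1L)
  shape <- d[1:3]
  X <- matrix(as.numeric(patch), prod(shape), d[4])
  if (d[4] != model$cfg@inChannels)
    stop(sprintf("model expects %d input channels, got %d",
                 model$cfg@inChannels, d[4]))
  out <- .unetForward(model, X, shape, train = FALSE)
  array(out$probs, c(shape, model$cfg@outClasses))
}

#' Freeze instance-normalization statistics
#'
#' Runs the network once on a reference input and stores the per-block
#' instance-norm mean and inverse standard deviation in the model. A model
#' with frozen statistics applies them at inference instead of recomputing
#' them from each input, which makes every layer's response to a voxel
#' independent of the rest of the input — the standard eval-mode
#' normalization semantics. In particular, an all-1x1x1-kernel network with
#' frozen statistics is strictly voxelwise, which is what makes exact
#' sliding-window/whole-volume equivalence checks possible.
#'
#' @param model a \code{UNet}.
#' @param refPatch reference input (3D array, or 4D with channels last)
#'   whose statistics are captured; spatial dims must suit the network.
#' @return The model with a populated \code{frozenStats} field.
#' @export
freezeNormStats <- function(model, refPatch) {
  d <- dim(refPatch)
  if (length(d) == 3L) d <- c(d, 1L)
  X <- matrix(as.numeric(refPatch), prod(d[1:3]), d[4])
  capture <- new.env(parent = emptyenv())
  .unetForward(model, X, d[1:3], train = FALSE, capture = capture)
  model$frozenStats <- as.list(capture)
  model
}
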