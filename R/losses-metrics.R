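# Dice-family metrics and the present-class batch Dice loss.
#
# DSC compares one (truth, prediction) pair of binary masks. DSCagg pools
# intersection and mask sizes over a whole set of pairs before dividing,
# which keeps patients with empty ground truth informative: their false
# positives inflate the pooled denominator instead of producing an
# uninformative per-patient DSC of 0.

.asBinary <- function(m, what) {
  v <- as.vector(m)
  if (!all(v %in% c(0, 1)))
    stop(sprintf("%s must be strictly binary (0/1)", what))
  v
}

#' Dice Similarity Coefficient for one pair of binary masks
#'
#' \code{2 |y & yhat| / (|y| + |yhat|)}. When the ground truth is empty and
#' the prediction is not (or vice versa) the score is 0. When both are empty
#' the score is the \code{emptyEmpty} convention, 1 by default: an empty
#' prediction of an empty truth is vacuously perfect.
#'
#' @param y binary ground-truth array/vector.
#' @param yhat binary predicted array/vector, congruent with \code{y}.
#' @param emptyEmpty value returned when both masks are empty.
#' @return Score in [0, 1].
#' @examples
#' y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
#' p <- c(1, 1, 1, 0, 1, 1, 1, 0, 0, 0)
#' dsc(y, p)  # 2 * 3 / (4 + 6) = 0.6
#' @export
dsc <- function(y, yhat, emptyEmpty = 1) {
  if (!identical(dim(y), dim(yhat)) || length(y) != length(yhat))
    stop("shape mismatch between y and yhat")
  yv <- .asBinary(y, "y"); pv <- .asBinary(yhat, "yhat")
  denom <- sum(yv) + sum(pv)
  if (denom == 0) return(emptyEmpty)
  2 * sum(yv * pv) / denom
}

#' Aggregated Dice Similarity Coefficient over a set of mask pairs
#'
#' \code{2 * sum_n |y_n & yhat_n| / sum_n (|y_n| + |yhat_n|)}: intersections
#' and mask sizes are pooled over all pairs before the ratio is taken. Pairs
#' whose ground truth is empty still contribute their predicted volume to
#' the denominator, penalizing false positives on tumor-free cases. With a
#' single pair of non-empty truth this reduces exactly to \code{\link{dsc}}.
#'
#' @param truths list of binary ground-truth masks.
#' @param preds list of binary predicted masks, pairwise congruent.
#' @param emptyEmpty value returned if every mask in every pair is empty.
#' @return Score in [0, 1].
#' @examples
#' dscAgg(list(rep(1, 10), rep(0, 5)), list(rep(1, 10), c(1, 1, 0, 0, 0)))
#' # (2 * 10) / (10 + 10 + 2) = 20/22
#' @export
dscAgg <- function(truths, preds, emptyEmpty = 1) {
  stopifnot(length(truths) == length(preds), length(truths) >= 1)
  num <- 0; denom <- 0
  for (n in seq_along(truths)) {
    if (!identical(dim(truths[[n]]), dim(preds[[n]])) ||
        length(truths[[n]]) != length(preds[[n]]))
      stop(sprintf("shape mismatch in pair %d", n))
    yv <- .asBinary(truths[[n]], "truth"); pv <- .asBinary(preds[[n]], "pred")
    num <- num + sum(yv * pv)
    denom <- denom + sum(yv) + sum(pv)
  }
  if (denom == 0) return(emptyEmpty)
  2 * num / denom
}

#' Per-class DSCagg of a multi-class label-mask cohort
#'
#' Binarizes each (truth, prediction) mask pair per class and computes
#' \code{\link{dscAgg}} for every class, plus the mean over the two target
#' classes (GTVp, GTVn) — the headline cohort score.
#'
#' @param truths list of integer label arrays (or LabelMask objects).
#' @param preds list of integer label arrays (or LabelMask objects).
#' @param classes integer vector of class labels to score.
#' @return Named numeric vector with one DSCagg per class and \code{mean}
#'   over the requested classes.
#' @export
dscAggPerClass <- function(truths, preds, classes = c(GTVp = 1, GTVn = 2)) {
  getLab <- function(x) if (is(x, "LabelMask")) x@labels else x
  truths <- lapply(truths, getLab); preds <- lapply(preds, getLab)
  out <- vapply(classes, function(cl) {
    dscAgg(lapply(truths, function(y) (y == cl) * 1),
           lapply(preds, function(p) (p == cl) * 1))
  }, numeric(1))
  c(out, mean = mean(out))
}

.diceEps <- 1e-7

# Pooled per-class sums for a batch: truths/probs are lists of (n x C)
# matrices (one-hot truth, probability simplex rows).
.batchClassSums <- function(truths, probs) {
  C <- ncol(truths[[1]])
  A <- numeric(C); By <- numeric(C); Bp <- numeric(C)
  for (n in seq_along(truths)) {
    A <- A + colSums(truths[[n]] * probs[[n]])
    By <- By + colSums(truths[[n]])
    Bp <- Bp + colSums(probs[[n]])
  }
  list(A = A, By = By, Bp = Bp, present = By > 0)
}

.asClassMatrix <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) return(as.matrix(x))
  matrix(x, prod(d[-length(d)]), d[length(d)])
}

#' Present-class batch Dice loss
#'
#' Soft-Dice training loss pooled over the whole batch. For each class c the
#' term \code{1 - 2 * sum(y * p) / (sum(y) + sum(p))} is computed with sums
#' running over every voxel of every batch example — the smooth analogue of
#' the aggregated Dice for that class. The returned loss is the mean of
#' these terms over the classes actually present in the batch's ground truth
#' (background included); absent classes contribute nothing, so a patch with
#' no GTVp voxels is never penalized for that class's ill-defined term. A
#' perfect prediction gives a loss of exactly 0.
#'
#' @param truths one-hot ground truth: a single array with the class axis
#'   last, or a list of such arrays (one per batch example).
#' @param probs predicted class probabilities, congruent with \code{truths}.
#' @return Loss value >= 0.
#' @export
diceLoss <- function(truths, probs) {
  if (!is.list(truths)) truths <- list(truths)
  if (!is.list(probs)) probs <- list(probs)
  truths <- lapply(truths, .asClassMatrix)
  probs <- lapply(probs, .asClassMatrix)
  s <- .batchClassSums(truths, probs)
  if (!any(s$present))
    stop("batch ground truth contains no class at all")
  terms <- 1 - 2 * s$A / (s$By + s$Bp + .diceEps)
  mean(terms[s$present])
}

# Loss and per-example gradient with respect to the probabilities.
.diceLossGrad <- function(truths, probs) {
  s <- .batchClassSums(truths, probs)
  B <- s$By + s$Bp + .diceEps
  terms <- 1 - 2 * s$A / B
  present <- s$present
  m <- sum(present)
  loss <- mean(terms[present])
  grads <- lapply(seq_along(probs), function(n) {
    g <- matrix(0, nrow(probs[[n]]), length(B))
    for (cl in which(present))
      g[, cl] <- (-2 / m) * (truths[[n]][, cl] * B[cl] - s$A[cl]) / B[cl]^2
    g
  })
  list(loss = loss, grads = grads)
}

#' Per-patient segmentation metrics and cohort DSCagg
#'
#' For every (truth, prediction) pair and each target class, computes the
#' per-patient DSC, precision and recall, and for the cohort the per-class
#' DSCagg plus its mean over target classes.
#'
#' @param truths list of integer label arrays or \code{LabelMask}s.
#' @param preds congruent list of predictions.
#' @param ids optional patient/image identifiers.
#' @param classes named integer vector of target classes.
#' @return A list with \code{perPatient} (data.frame: id, class, dsc,
#'   precision, recall) and \code{cohort} (named DSCagg vector).
#' @export
evaluateSegmentation <- function(truths, preds, ids = NULL,
                                 classes = c(GTVp = 1, GTVn = 2)) {
  getLab <- function(x) if (is(x, "LabelMask")) x@labels else x
  truths <- lapply(truths, getLab); preds <- lapply(preds, getLab)
  if (is.null(ids)) ids <- sprintf("case%03d", seq_along(truths))
  rows <- list()
  for (n in seq_along(truths)) {
    for (ci in seq_along(classes)) {
      y <- (truths[[n]] == classes[ci]) * 1
      p <- (preds[[n]] == classes[ci]) * 1
      tp <- sum(y * p)
      prec <- if (sum(p) > 0) tp / sum(p) else NA_real_
      rec <- if (sum(y) > 0) tp / sum(y) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        id = ids[n], class = names(classes)[ci], dsc = dsc(y, p),
        precision = prec, recall = rec, stringsAsFactors = FALSE)
    }
  }
  list(perPatient = do.call(rbind, rows),
       cohort = dscAggPerClass(truths, preds, classes))
}
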