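# Loss terms of the adversarial segmentation objective. All spatial sums are
# means, so values are invariant to batch and image size; probabilities are
# clamped to [1e-7, 1 - 1e-7] before any logarithm. Each loss has a companion
# gradient used by the training engine.

EPS_LOG <- 1e-7

check_same_shape <- function(a, b, na = "pred", nb = "target") {
  if (!identical(dim_or_len(a), dim_or_len(b))) {
    stop(sprintf("`%s` and `%s` must have identical shapes", na, nb))
  }
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-[y log(p) + (1 - y) log(1 - p)]`, with probabilities
#' clamped at 1e-7.
#'
#' @param pred predicted probabilities in \[0, 1\].
#' @param target binary ground-truth mask of the same shape.
#' @return non-negative scalar.
#' @export
bce_loss <- function(pred, target) {
  check_same_shape(pred, target)
  p <- clamp(pred, EPS_LOG, 1 - EPS_LOG)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

bce_grad <- function(pred, target) {
  p <- clamp(pred, EPS_LOG, 1 - EPS_LOG)
  g <- (-target / p + (1 - target) / (1 - p)) / length(pred)
  array(g, dim = dim_or_len(pred))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*y) + eps) / (sum(p) + sum(y) + eps)`, computed per image
#' and averaged over the batch. Accepts soft predictions.
#'
#' @inheritParams bce_loss
#' @param eps smoothing constant keeping the ratio defined for empty masks.
#' @return scalar in \[0, 1\] (up to smoothing).
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  check_same_shape(pred, target)
  if (is.null(dim(pred)) || length(dim(pred)) < 3L) {
    inter <- sum(pred * target)
    return(1 - (2 * inter + eps) / (sum(pred) + sum(target) + eps))
  }
  B <- dim(pred)[1L]
  v <- 0
  for (b in seq_len(B)) {
    p <- batch_slice(pred, b); y <- batch_slice(target, b)
    v <- v + 1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)
  }
  v / B
}

dice_grad <- function(pred, target, eps = 1e-6) {
  d <- dim(pred)
  g <- array(0, dim = d)
  B <- d[1L]
  for (b in seq_len(B)) {
    p <- batch_slice(pred, b); y <- batch_slice(target, b)
    num <- 2 * sum(p * y) + eps
    den <- sum(p) + sum(y) + eps
    g[b, , , ] <- -(2 * y * den - num) / den^2 / B
  }
  g
}

#' Adversarial loss for the segmentor
#'
#' Mean over patch positions of `-log(score)` on scores of (image, prediction)
#' pairs; low when the discriminator is fooled into calling predictions real.
#'
#' @param fake_scores discriminator patch scores on (image, prediction) pairs.
#' @return non-negative scalar.
#' @export
adversarial_loss <- function(fake_scores) {
  -mean(log(clamp(fake_scores, EPS_LOG, 1 - EPS_LOG)))
}

adversarial_grad <- function(fake_scores) {
  s <- clamp(fake_scores, EPS_LOG, 1 - EPS_LOG)
  array(-1 / (s * length(fake_scores)), dim = dim_or_len(fake_scores))
}

#' Discriminator loss
#'
#' Spatial binary cross-entropy with label 0 for prediction (fake) patches and
#' 1 for ground-truth (real) patches: mean `-log(1 - fake)` plus mean
#' `-log(real)`. On unlabeled batches no real pair exists and the real term is
#' omitted (`real_scores = NULL`).
#'
#' @param fake_scores patch scores on (image, prediction) pairs.
#' @param real_scores patch scores on (image, ground truth) pairs, or `NULL`.
#' @return non-negative scalar.
#' @export
discriminator_loss <- function(fake_scores, real_scores = NULL) {
  if (is.null(fake_scores) && is.null(real_scores)) {
    stop("at least one of fake_scores and real_scores must be given")
  }
  v <- 0
  if (!is.null(fake_scores)) {
    v <- v - mean(log(1 - clamp(fake_scores, EPS_LOG, 1 - EPS_LOG)))
  }
  if (!is.null(real_scores)) {
    v <- v - mean(log(clamp(real_scores, EPS_LOG, 1 - EPS_LOG)))
  }
  v
}

discriminator_grad <- function(fake_scores, real_scores = NULL) {
  out <- list(fake = NULL, real = NULL)
  if (!is.null(fake_scores)) {
    s <- clamp(fake_scores, EPS_LOG, 1 - EPS_LOG)
    out$fake <- array(1 / ((1 - s) * length(fake_scores)), dim = dim_or_len(fake_scores))
  }
  if (!is.null(real_scores)) {
    s <- clamp(real_scores, EPS_LOG, 1 - EPS_LOG)
    out$real <- array(-1 / (s * length(real_scores)), dim = dim_or_len(real_scores))
  }
  out
}

#' Joint segmentor loss on labeled data
#'
#' Unweighted sum (by default) of the pixel BCE, soft Dice and adversarial
#' terms. Optional weights are exposed for ablations only.
#'
#' @inheritParams bce_loss
#' @param fake_scores discriminator scores of the (image, prediction) pair.
#' @param weights named vector with entries `bce`, `dice`, `adv`.
#' @return list with the three components and their weighted sum `joint`.
#' @export
joint_loss <- function(pred, target, fake_scores,
                       weights = c(bce = 1, dice = 1, adv = 1)) {
  l_bce <- bce_loss(pred, target)
  l_dice <- dice_loss(pred, target)
  l_adv <- adversarial_loss(fake_scores)
  list(bce = l_bce, dice = l_dice, adv = l_adv,
       joint = weights[["bce"]] * l_bce + weights[["dice"]] * l_dice +
         weights[["adv"]] * l_adv)
}

#' Compose the semi-supervised loss
#'
#' Supervised part = joint segmentor loss + discriminator loss on labeled
#' data; unsupervised part = adversarial loss on unlabeled data; total is
#' their sum. With no unlabeled batch the total reduces to the supervised
#' loss.
#'
#' @param labeled list with elements `joint` and `d` (scalars) from a labeled
#'   batch.
#' @param unlabeled list with element `adv` from an unlabeled batch, or `NULL`.
#' @return list with `supervised`, `unsupervised` and `total`.
#' @export
semi_losses <- function(labeled, unlabeled = NULL) {
  if (is.null(labeled)) stop("semi-supervised training requires labeled data")
  supervised <- labeled$joint + labeled$d
  unsupervised <- if (is.null(unlabeled)) 0 else unlabeled$adv
  list(supervised = supervised, unsupervised = unsupervised,
       total = supervised + unsupervised)
}
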