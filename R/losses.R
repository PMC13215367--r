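# Training objective: Dice + cross-entropy + patch-level focal loss.
#
# The segmentation loss is
#   L = L_Dice + (1 - w) * L_CE + w * L_LRP
# where L_LRP ("local region perceptron") is a focal classification loss
# over non-overlapping patches (default 8x8x8 voxels).  A patch is
# labeled positive when it contains at least one lesion voxel; its
# predicted presence probability q_l aggregates the voxel foreground
# probabilities inside it.  The focal weight (1-q)^gamma concentrates
# gradient on hard positive patches while easy background patches are
# down-weighted, countering the extreme foreground-background imbalance
# that a voxel-wise loss sees when lesions occupy a handful of voxels in
# a multi-million voxel volume.
#
# All losses accept plain numeric arrays (returning a plain scalar) or
# autograd nodes (returning a node usable for backpropagation).

#' Loss configuration
#'
#' Bundles the tunable parameters of the composite segmentation loss.
#'
#' @param w Mixing weight of the patch-focal (LRP) term against
#'   cross-entropy, in `[0, 1]`. The composite loss is
#'   `L_Dice + (1 - w) * L_CE + w * L_LRP`; `w = 0.4` balances
#'   small-lesion sensitivity against precision.
#' @param gamma Focusing parameter of the focal term (`>= 0`); default 0.5.
#' @param patch_size Edge length in voxels of the cubic patches; must
#'   divide each volume axis. Default 8.
#' @param smooth Dice stabilizer added to numerator and denominator.
#' @param aggregate How voxel probabilities aggregate into a patch
#'   presence probability: `"max"` (default) or `"noisyor"`
#'   (\eqn{1 - \prod (1 - p)}).
#' @param two_sided If `TRUE` (default) the focal term penalizes both
#'   positive and negative patches (standard binary focal loss); if
#'   `FALSE` only positive patches contribute.
#' @return A list of class `"loss_config"`.
#' @export
loss_config <- function(w = 0.4, gamma = 0.5, patch_size = 8L, smooth = 1e-5,
                        aggregate = c("max", "noisyor"), two_sided = TRUE) {
  aggregate <- match.arg(aggregate)
  stopifnot(w >= 0, w <= 1, gamma >= 0, patch_size >= 1, smooth > 0)
  structure(list(w = w, gamma = gamma, patch_size = as.integer(patch_size),
                 smooth = smooth, aggregate = aggregate, two_sided = two_sided),
            class = "loss_config")
}

.check_same_shape <- function(a, b) {
  da <- dim(vof(a)) %||% length(vof(a))
  db <- dim(vof(b)) %||% length(vof(b))
  if (!identical(as.integer(da), as.integer(db)))
    stop("shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * gt) + smooth) / (sum(pred) + sum(gt) + smooth)`;
#' zero iff the (binary) prediction equals the ground truth.
#'
#' @param pred Per-voxel foreground probability, 3D array (or autograd node).
#' @param gt Binary ground-truth mask, same shape.
#' @param smooth Stabilizer, default `1e-5`.
#' @return Scalar loss in `[0, 1]` (numeric, or node if `pred` is a node).
#' @export
dice_loss <- function(pred, gt, smooth = 1e-5) {
  .check_same_shape(pred, gt)
  gt <- vof(gt)
  num <- ag_add(ag_mul(ag_sum(ag_mul(pred, gt)), 2), smooth)
  den <- ag_add(ag_add(ag_sum(pred), sum(gt)), smooth)
  ag_sub(1, ag_div(num, den))
}

#' Cross-entropy loss
#'
#' Mean over voxels of `-log p(correct class)`, with probabilities
#' clamped away from 0 for numerical safety.
#'
#' @param pred Either a 3D array of foreground probabilities or a 4D
#'   array of per-voxel class probabilities with classes
#'   (background, foreground) along the last dimension.
#' @param gt Binary ground-truth mask.
#' @param clamp Lower clamp for probabilities before the log.
#' @return Scalar loss `>= 0`.
#' @export
ce_loss <- function(pred, gt, clamp = 1e-7) {
  gt <- vof(gt)
  pv <- vof(pred)
  if (length(dim(pv)) == 4L) {
    stopifnot(identical(as.integer(dim(pv)[1:3]), as.integer(dim(gt))))
    pc <- ag_add(ag_mul(ag_channel(pred, 2L), gt),
                 ag_mul(ag_channel(pred, 1L), 1 - gt))
  } else {
    .check_same_shape(pred, gt)
    pc <- ag_add(ag_mul(pred, gt), ag_mul(ag_sub(1, pred), 1 - gt))
  }
  ag_neg(ag_mean(ag_log(ag_clamp(pc, clamp, 1))))
}

#' Patch presence labels
#'
#' Partitions the mask into non-overlapping cubic patches and labels a
#' patch 1 iff it contains at least one lesion voxel.
#'
#' @param gt Binary 3D mask; each axis must be divisible by `patch_size`.
#' @param patch_size Patch edge length in voxels (default 8).
#' @return 3D array of 0/1 labels over the patch grid.
#' @export
patch_labels <- function(gt, patch_size = 8L) {
  gt <- vof(gt)
  d <- dim(gt)
  if (any(d %% patch_size != 0))
    stop("patch_size ", patch_size, " does not divide volume shape ",
         paste(d, collapse = "x"))
  q <- .patchmax_fwd(gt + 0, dim(gt), as.integer(patch_size))$q
  (q > 0) + 0
}

#' Patch presence probabilities
#'
#' Aggregates per-voxel foreground probabilities into one presence
#' probability per patch: the patch maximum (default) or noisy-OR.
#' Differentiable with respect to `pred` when given an autograd node.
#'
#' @inheritParams patch_labels
#' @param pred Per-voxel foreground probability, 3D array or node.
#' @param aggregate `"max"` or `"noisyor"`.
#' @return 3D array (or node) of probabilities over the patch grid.
#' @export
patch_probs <- function(pred, patch_size = 8L, aggregate = c("max", "noisyor")) {
  aggregate <- match.arg(aggregate)
  d <- dim(vof(pred))
  if (any(d %% patch_size != 0))
    stop("patch_size ", patch_size, " does not divide volume shape ",
         paste(d, collapse = "x"))
  if (aggregate == "max") return(ag_patchmax(pred, patch_size))
  # noisy-OR: 1 - prod(1 - p) via a patch-sum of log(1 - p)
  p <- as.integer(patch_size)
  l1m <- ag_log(ag_clamp(ag_sub(1, pred), 1e-12, 1))
  x4 <- ag_reshape(l1m, c(d, 1L))
  w1 <- array(1, dim = c(p, p, p, 1L, 1L))
  s4 <- ag_conv3(x4, w1, 0, stride = p, pad = 0L)
  gdim <- d %/% p
  ag_sub(1, ag_exp(ag_reshape(s4, gdim)))
}

#' Patch-level focal (LRP) loss
#'
#' Mean over patches of the focal classification loss
#' \deqn{-[y (1-q)^\gamma \log q + (1-y)\, q^\gamma \log(1-q)]}
#' with probabilities clamped to `[1e-7, 1 - 1e-7]` before the logs.
#' With `two_sided = FALSE` only the positive-patch term is kept.
#'
#' @param y Binary patch labels (array over the patch grid).
#' @param q Patch presence probabilities, same shape (array or node).
#' @param gamma Focusing parameter, `>= 0`.
#' @param two_sided Include the negative-patch term (default `TRUE`).
#' @return Scalar loss `>= 0`.
#' @export
lrp_loss <- function(y, q, gamma = 0.5, two_sided = TRUE) {
  if (gamma < 0) stop("gamma must be >= 0")
  .check_same_shape(y, q)
  y <- vof(y)
  qc <- ag_clamp(q, 1e-7, 1 - 1e-7)
  pos <- ag_mul(ag_mul(ag_pow(ag_sub(1, qc), gamma), ag_log(qc)), y)
  term <- pos
  if (two_sided) {
    neg <- ag_mul(ag_mul(ag_pow(qc, gamma), ag_log(ag_sub(1, qc))), 1 - y)
    term <- ag_add(pos, neg)
  }
  ag_neg(ag_mean(term))
}

#' Composite segmentation loss
#'
#' `L_Dice + (1 - w) * L_CE + w * L_LRP`, the full training objective.
#' At `w = 0` it reduces exactly to Dice + cross-entropy; the LRP term
#' is built from [patch_labels()] on the ground truth and
#' [patch_probs()] on the prediction.
#'
#' @param pred Per-voxel class probabilities: 4D array (classes last) or
#'   3D foreground-probability array; may be an autograd node.
#' @param gt Binary ground-truth mask.
#' @param config A [loss_config()].
#' @return Scalar loss (numeric or node).
#' @export
composite_loss <- function(pred, gt, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  gt <- vof(gt)
  fg <- if (length(dim(vof(pred))) == 4L) ag_channel(pred, 2L) else pred
  ld <- dice_loss(fg, gt, config$smooth)
  lc <- ce_loss(pred, gt)
  y <- patch_labels(gt, config$patch_size)
  q <- patch_probs(fg, config$patch_size, config$aggregate)
  ll <- lrp_loss(y, q, config$gamma, config$two_sided)
  ag_add(ld, ag_add(ag_mul(lc, 1 - config$w), ag_mul(ll, config$w)))
}
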