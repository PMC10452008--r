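# Segmentation losses.  The class-wise dice loss (CDL) computes a soft dice
# similarity on the foreground for lesion-bearing patches and on the
# background for lesion-free patches, so that any predicted foreground on a
# negative patch is punished -- the failure mode of the plain dice loss, which
# receives no penalty for false positives when the ground truth is empty.

check_loss_inputs <- function(pred, truth, patch_label = NULL) {
  if (!identical(dim(pred), dim(truth)) &&
      !(is.null(dim(pred)) && is.null(dim(truth)) &&
        length(pred) == length(truth))) {
    stop("prediction and ground truth shapes differ: ",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"))
  }
  if (any(pred < 0 | pred > 1)) {
    stop("predicted probabilities must lie in [0, 1]")
  }
  if (!all(truth %in% c(0, 1))) {
    stop("ground-truth mask must be binary (0/1)")
  }
  if (!is.null(patch_label)) {
    has_fg <- any(truth > 0)
    if (!patch_label %in% c(0, 1)) stop("patch label must be 0 or 1")
    if ((patch_label == 1) != has_fg) {
      stop("patch label (", patch_label, ") inconsistent with the mask (",
           if (has_fg) "has" else "has no", " foreground pixels)")
    }
  }
  invisible(TRUE)
}

#' Soft dice loss
#'
#' `1 - (2 * sum(y * p) + eps) / (sum(y) + sum(p) + eps)`.  With an empty
#' ground truth this loss rewards an all-background prediction only through
#' the stabilizer, i.e. it barely punishes false positives -- the pathology
#' the class-wise variant fixes.
#'
#' @param pred predicted foreground probabilities in `[0, 1]`.
#' @param truth binary ground-truth mask, same shape.
#' @param eps stabilizer keeping the ratio (and its gradient) finite.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, truth, eps = 1e-6) {
  check_loss_inputs(pred, truth)
  1 - (2 * sum(truth * pred) + eps) / (sum(truth) + sum(pred) + eps)
}

#' Class-wise dice loss
#'
#' For a positive patch (`patch_label = 1`) the loss is one minus the soft
#' dice of the foreground; for a negative patch it is one minus the soft dice
#' of the background, so every predicted foreground pixel on a lesion-free
#' patch increases the loss and training drives negative patches toward an
#' all-zero mask.
#'
#' @param pred predicted foreground probabilities in `[0, 1]`.
#' @param truth binary ground-truth mask, same shape.
#' @param patch_label 0/1 image-level lesion label; derived from `truth`
#'   (any foreground pixel present) when `NULL`, validated against it
#'   otherwise.
#' @param eps stabilizer.
#' @return scalar loss in `[0, 1]`.
#' @export
class_wise_dice_loss <- function(pred, truth, patch_label = NULL,
                                 eps = 1e-6) {
  if (is.null(patch_label)) patch_label <- as.numeric(any(truth > 0))
  check_loss_inputs(pred, truth, patch_label)
  d_fg <- (2 * sum(truth * pred) + eps) / (sum(truth) + sum(pred) + eps)
  d_bg <- (2 * sum((1 - truth) * (1 - pred)) + eps) /
    (sum(1 - truth) + sum(1 - pred) + eps)
  1 - (patch_label * d_fg + (1 - patch_label) * d_bg)
}

#' Literal per-pixel reading of the class-wise dice formula
#'
#' The class-wise loss is typeset in its source as a sum over per-pixel
#' ratios.  That literal expression does not reduce to a dice similarity
#' coefficient (its positive term vanishes for binary inputs where prediction
#' and truth agree pixel-wise only through 1/2 factors, and the sum is not
#' normalized); it is provided solely for comparison with the aggregated form
#' implemented in [class_wise_dice_loss()].
#'
#' @inheritParams class_wise_dice_loss
#' @return scalar value of the literal expression.
#' @export
cdl_literal <- function(pred, truth, patch_label = NULL, eps = 1e-6) {
  if (is.null(patch_label)) patch_label <- as.numeric(any(truth > 0))
  check_loss_inputs(pred, truth, patch_label)
  term <- patch_label * truth * pred / (truth + pred + eps) +
    ((1 - patch_label) * (1 - truth) * (1 - pred) + eps) /
      ((1 - truth) + (1 - pred) + eps)
  1 - sum(term)
}

## ---- differentiable (tensor) versions ----------------------------------------

#' Differentiable dice / class-wise dice losses
#'
#' Tensor versions of [dice_loss()] and [class_wise_dice_loss()] used by the
#' training loop: `pred` is a `tg_tensor` of foreground probabilities and the
#' returned scalar node supports [tg_backward()].  Gradients are finite for
#' any prediction in `[0, 1]`, including all-zero and all-one, because the
#' stabilizer keeps every denominator positive.
#'
#' @param pred `tg_tensor` of foreground probabilities.
#' @param truth plain binary array of the same shape.
#' @param patch_label 0/1 image-level label (`NULL`: derived from `truth`).
#' @param eps stabilizer.
#' @return scalar `tg_tensor`.
#' @export
dice_loss_t <- function(pred, truth, eps = 1e-6) {
  y <- tg_tensor(array(as.numeric(truth), dim = dim(pred$v)))
  inter <- tg_sum(tg_mul(pred, y))
  den <- tg_add(tg_add(tg_sum(y), tg_sum(pred)), eps)
  tg_sub(tg_smul(tg_div(tg_add(tg_smul(inter, 2), eps), den), -1), -1)
}

#' @rdname dice_loss_t
#' @export
class_wise_dice_loss_t <- function(pred, truth, patch_label = NULL,
                                   eps = 1e-6) {
  if (is.null(patch_label)) patch_label <- as.numeric(any(truth > 0))
  check_loss_inputs(pred$v, array(as.numeric(truth), dim = dim(pred$v)),
                    patch_label)
  npix <- length(truth)
  y <- tg_tensor(array(as.numeric(truth), dim = dim(pred$v)))
  sp <- tg_sum(pred)
  if (patch_label == 1) {
    inter <- tg_sum(tg_mul(pred, y))
    den <- tg_add(tg_add(sp, eps), sum(truth))
    d <- tg_div(tg_add(tg_smul(inter, 2), eps), den)
  } else {
    # y is all zero on a negative patch, so
    # D_bg = (2 * (N - sum(p)) + eps) / (2N - sum(p) + eps)
    num <- tg_add(tg_smul(sp, -2), 2 * npix + eps)
    den <- tg_add(tg_smul(sp, -1), 2 * npix + eps)
    d <- tg_div(num, den)
  }
  tg_sub(tg_smul(d, -1), -1)
}
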