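# Segmentation and classification evaluation metrics.

#' Segmentation overlap metrics
#'
#' `DSC = 2|S.T| / (|S| + |T|)`, `IoU = |S.T| / |S u T|`, segmentation
#' precision `|S.T| / |S|` and recall `|S.T| / |T|`, with `S` the predicted
#' and `T` the ground-truth mask.  When both masks are empty all four are
#' defined as 1 (nothing to find, nothing found).
#'
#' @param S predicted binary mask.
#' @param T_ ground-truth binary mask of the same shape.
#' @return named numeric vector `dsc`, `iou`, `precision`, `recall`.
#' @export
segmentation_metrics <- function(S, T_) {
  if (!identical(dim(S), dim(T_)))
    stop("segmentation_metrics: mask shapes differ")
  if (!all(S %in% c(0, 1)) || !all(T_ %in% c(0, 1)))
    stop("segmentation_metrics: masks must be binary")
  i <- sum(S * T_)
  s <- sum(S); t <- sum(T_)
  u <- s + t - i
  if (s == 0 && t == 0)
    return(c(dsc = 1, iou = 1, precision = 1, recall = 1))
  c(dsc = 2 * i / (s + t),
    iou = if (u > 0) i / u else 1,
    precision = if (s > 0) i / s else 0,
    recall = if (t > 0) i / t else 0)
}

#' Classification metrics with DM as the positive class
#'
#' Standard confusion-matrix metrics: accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' and F1 as the harmonic mean of precision and recall.
#'
#' @param pred integer predicted labels (0/1).
#' @param truth integer true labels (0/1), same length.
#' @param positive label value treated as positive (1 = DM).
#' @return named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(pred, truth, positive = 1) {
  if (length(pred) == 0 || length(pred) != length(truth))
    stop("classification_metrics: need equal-length nonempty label vectors")
  tp <- sum(pred == positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = (tp + tn) / length(pred), precision = prec,
    recall = rec, f1 = f1)
}

#' Combined segmentation + classification loss
#'
#' `alpha * DiceLoss(seg_logits, mask) + beta * CrossEntropy(Y_prob, Y)`;
#' reduces to the pure Dice loss at `beta = 0`.
#'
#' @param seg_logits segmentation logits array (see [dice_loss()]).
#' @param mask binary ground-truth mask.
#' @param Y_prob predicted class probability matrix.
#' @param Y one-hot (or integer) class targets.
#' @param alpha,beta loss weights (defaults 0.6 / 0.4).
#' @return scalar loss.
#' @export
combined_loss <- function(seg_logits, mask, Y_prob, Y,
                          alpha = 0.6, beta = 0.4) {
  seg <- dice_loss(seg_logits, mask)
  cls <- if (beta == 0) 0 else elm_loss(Y_prob, Y)
  alpha * seg + beta * cls
}
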