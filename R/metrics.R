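# Evaluation suite: dice similarity coefficient (DSC), Jaccard index (JI),
# relative volume difference (RVD) on mask pairs; TPR/FPR/precision/pixel
# accuracy from confusion counts; rank-based ROC AUC; and the test-set
# aggregation that produces the six-column report (DSC, AUC, PA, JI, RVD,
# Precision).

check_mask_pair <- function(annotation, prediction) {
  if (!identical(dim(annotation), dim(prediction))) {
    stop("annotation and prediction shapes differ: ",
         paste(dim(annotation), collapse = "x"), " vs ",
         paste(dim(prediction), collapse = "x"))
  }
  if (!all(annotation %in% c(0, 1)) || !all(prediction %in% c(0, 1))) {
    stop("masks must be binary (0/1)")
  }
  invisible(TRUE)
}

#' Segmentation overlap metrics on a mask pair
#'
#' `dsc` is `2|A∩P| / (|A|+|P|)`, `jaccard` is `|A∩P| / (|A∪P|)`, and `rvd`
#' is the relative volume difference `(|P|-|A|) / |A|`.  When both masks are
#' empty, DSC and JI are 1 by convention (a correct negative segmentation);
#' RVD is undefined for an empty annotation and returns `NA` with a warning
#' (such images are excluded from aggregation).
#'
#' @param annotation binary ground-truth mask.
#' @param prediction binary predicted mask of the same shape.
#' @return a single numeric value.
#' @export
dsc <- function(annotation, prediction) {
  check_mask_pair(annotation, prediction)
  na <- sum(annotation); np <- sum(prediction)
  if (na + np == 0) return(1)
  2 * sum(annotation * prediction) / (na + np)
}

#' @rdname dsc
#' @export
jaccard <- function(annotation, prediction) {
  check_mask_pair(annotation, prediction)
  inter <- sum(annotation * prediction)
  uni <- sum(annotation) + sum(prediction) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' @rdname dsc
#' @export
rvd <- function(annotation, prediction) {
  check_mask_pair(annotation, prediction)
  na <- sum(annotation)
  if (na == 0) {
    warning("RVD is undefined for an empty annotation; returning NA")
    return(NA_real_)
  }
  (sum(prediction) - na) / na
}

#' Confusion counts and derived rates at a score threshold
#'
#' Classifies each instance as positive when `score > threshold` and tallies
#' TP/FP/TN/FN against the 0/1 labels.  TPR = TP/(TP+FN), FPR = FP/(FP+TN),
#' Precision = TP/(TP+FP) and PA = (TP+TN)/total, with the 0/0 -> 0
#' convention for empty denominators.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels, same length.
#' @param threshold decision threshold.
#' @return list with `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`, `precision`, `pa`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pred <- as.numeric(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  safe <- function(num, den) if (den == 0) 0 else num / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       tpr = safe(tp, tp + fn), fpr = safe(fp, fp + tn),
       precision = safe(tp, tp + fp),
       pa = safe(tp + tn, tp + tn + fp + fn))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimate of `P(X1 > X0)` with ties counted 1/2,
#' which equals the trapezoidal area under the ROC curve and is invariant to
#' strictly monotone transforms of the scores.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; at least one of each class is required.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC is undefined without both a positive and a negative instance")
  }
  r <- rank(scores)  # midranks handle ties with 1/2 credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a test set
#'
#' Computes the six-column report.  Conventions: DSC and JI are averaged over
#' images with a non-empty annotation; RVD likewise.  Image-level
#' classification scores are the predicted lesion-pixel fractions; an image is
#' called positive when its fraction exceeds `tau`.  PA and Precision come
#' from the image-level confusion table (pixel-level PA is also reported), and
#' AUC from the image-level scores (NA when the labels are single-class).
#'
#' @param predictions list of binary predicted masks.
#' @param annotations list of binary ground-truth masks (same shapes).
#' @param image_labels optional 0/1 image labels; derived from the annotations
#'   when `NULL`.
#' @param tau positive-call threshold on the predicted lesion-pixel fraction.
#' @return a `metrics_report` list with fields `dsc`, `auc`, `pa`, `ji`,
#'   `rvd`, `precision`, plus `pixel_pa`, per-image tables and the
#'   aggregation conventions.
#' @export
evaluate_testset <- function(predictions, annotations, image_labels = NULL,
                             tau = 1e-3) {
  if (length(predictions) != length(annotations)) {
    stop("predictions (", length(predictions), ") and annotations (",
         length(annotations), ") are misaligned")
  }
  n <- length(predictions)
  if (is.null(image_labels)) {
    image_labels <- vapply(annotations, function(a) as.numeric(any(a > 0)),
                           numeric(1))
  }
  if (length(image_labels) != n) {
    stop("image_labels length (", length(image_labels),
         ") does not match the number of images (", n, ")")
  }
  per_dsc <- numeric(n); per_ji <- numeric(n); per_rvd <- rep(NA_real_, n)
  score <- numeric(n)
  pix_correct <- 0; pix_total <- 0
  positive_ann <- logical(n)
  for (i in seq_len(n)) {
    a <- annotations[[i]]; p <- predictions[[i]]
    check_mask_pair(a, p)
    per_dsc[i] <- dsc(a, p)
    per_ji[i] <- jaccard(a, p)
    positive_ann[i] <- any(a > 0)
    if (positive_ann[i]) per_rvd[i] <- rvd(a, p)
    score[i] <- mean(p)
    pix_correct <- pix_correct + sum(a == p)
    pix_total <- pix_total + length(a)
  }
  cls <- confusion(score, image_labels, threshold = tau)
  auc_val <- if (length(unique(image_labels)) == 2L) {
    auc(score, image_labels)
  } else NA_real_
  rep_ <- list(
    dsc = mean(per_dsc[positive_ann]),
    auc = auc_val,
    pa = cls$pa,
    ji = mean(per_ji[positive_ann]),
    rvd = mean(per_rvd[positive_ann]),
    precision = cls$precision,
    pixel_pa = pix_correct / pix_total,
    n_images = n,
    n_positive = sum(image_labels == 1),
    image_scores = score,
    image_labels = image_labels,
    per_image = data.frame(dsc = per_dsc, ji = per_ji, rvd = per_rvd,
                           score = score, label = image_labels),
    conventions = paste(
      "DSC/JI/RVD averaged over images with non-empty annotations;",
      "image called positive when predicted lesion fraction > tau =", tau,
      "; AUC/PA/Precision at image level; ties in AUC get 1/2 credit")
  )
  class(rep_) <- "metrics_report"
  rep_
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Test set: %d images (%d positive)\n DSC %.4f | AUC %s | PA %.4f | JI %.4f | RVD %s | Precision %.4f\n",
    x$n_images, x$n_positive, x$dsc,
    ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)), x$pa, x$ji,
    ifelse(is.na(x$rvd), "NA", sprintf("%.4f", x$rvd)), x$precision))
  cat(" pixel-level PA", sprintf("%.4f", x$pixel_pa), "\n")
  invisible(x)
}

#' Write a metrics report as JSON and TSV
#'
#' @param report a `metrics_report`.
#' @param json_path,tsv_path output paths (either may be `NULL` to skip).
#' @return the report, invisibly.
#' @export
write_metrics_report <- function(report, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  cols <- c("dsc", "auc", "pa", "ji", "rvd", "precision", "pixel_pa")
  if (!is.null(json_path)) {
    jsonlite::write_json(report[cols], json_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(metric = cols,
                     value = unlist(report[cols], use.names = FALSE))
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
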