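# Segmentation evaluation: confusion counts, overlap scores and rates.
#
# Two aggregation policies are computed side by side: per_image_mean
# averages per-image dice/mIoU over the evaluation set, global_pixels pools
# the confusion counts over all pixels first.  On pooled counts F1 and dice
# coincide algebraically (both are 2TP / (2TP + FP + FN)); on per-image
# means they generally differ, which is why both are reported.

check_mask_pair <- function(y_true, y_pred) {
  if (!identical(dim(y_true), dim(y_pred)) ||
      length(y_true) != length(y_pred))
    stop("masks must have congruent shapes")
  if (any(y_true != 0 & y_true != 1) || any(y_pred != 0 & y_pred != 1))
    stop("masks must be binary (0/1)")
  invisible(TRUE)
}

#' Pixel confusion counts of a binary mask pair
#'
#' @param y_true,y_pred binary masks (0/1), congruent shapes.
#' @return named list `TP`, `FP`, `TN`, `FN` summing to the pixel count.
#' @export
confusion_counts <- function(y_true, y_pred) {
  check_mask_pair(y_true, y_pred)
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Dice coefficient and intersection-over-union of two binary masks
#'
#' `dsc = 2|Y ∩ Yhat| / (|Y| + |Yhat|)`, `miou = |Y ∩ Yhat| / |Y ∪ Yhat|`.
#' When both masks are empty, both scores are defined as 1 (correct
#' rejection of absent foreground). The two are linked by
#' `miou = dsc / (2 - dsc)`.
#'
#' @inheritParams confusion_counts
#' @return named list `dsc`, `miou`.
#' @export
overlap_metrics <- function(y_true, y_pred) {
  check_mask_pair(y_true, y_pred)
  inter <- sum(y_true == 1 & y_pred == 1)
  a <- sum(y_true == 1); b <- sum(y_pred == 1)
  if (a + b == 0) return(list(dsc = 1, miou = 1))
  list(dsc = 2 * inter / (a + b), miou = inter / (a + b - inter))
}

#' Precision, recall, specificity and F1 from confusion counts
#'
#' `pr = TP/(TP+FP)`, `re = TP/(TP+FN)`, `sp = TN/(TN+FP)`,
#' `f1 = 2*pr*re/(pr+re)`. A zero denominator yields 0 with a warning.
#'
#' @param counts a [confusion_counts()] result (or any list with TP, FP,
#'   TN, FN).
#' @return named list `pr`, `re`, `sp`, `f1`, fractions in `[0, 1]`.
#' @export
rate_metrics <- function(counts) {
  safe <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0")
      return(0)
    }
    num / den
  }
  pr <- safe(counts$TP, counts$TP + counts$FP, "precision")
  re <- safe(counts$TP, counts$TP + counts$FN, "recall")
  sp <- safe(counts$TN, counts$TN + counts$FP, "specificity")
  f1 <- safe(2 * pr * re, pr + re, "F1")
  list(pr = pr, re = re, sp = sp, f1 = f1)
}

#' Evaluate a set of probability maps against truth masks
#'
#' Binarizes predictions at `threshold`, then reports all six metrics under
#' both aggregation policies: `per_image_mean` (dice/mIoU averaged over
#' images; rates from per-image means of pr/re/sp/f1) and `global_pixels`
#' (confusion counts pooled over all pixels first).
#'
#' @param predictions list of probability maps in `[0, 1]`.
#' @param truths list of binary masks, congruent with `predictions`.
#' @param threshold binarization threshold in (0, 1).
#' @return object of class `tmd_metrics_report`: a data frame with one row
#'   per aggregation policy and columns dsc, f1, miou, re, pr, sp
#'   (fractions in `[0, 1]`).
#' @export
evaluate_set <- function(predictions, truths, threshold = 0.5) {
  if (length(predictions) == 0L) stop("empty prediction set")
  if (length(predictions) != length(truths))
    stop("predictions and truths differ in length")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")

  bin <- lapply(predictions, function(p) (p >= threshold) * 1L)
  per <- lapply(seq_along(bin), function(i) {
    ov <- overlap_metrics(truths[[i]], bin[[i]])
    rt <- rate_metrics(confusion_counts(truths[[i]], bin[[i]]))
    c(dsc = ov$dsc, miou = ov$miou, rt)
  })
  per_mean <- colMeans(do.call(rbind, lapply(per, function(p)
    unlist(p)[c("dsc", "f1", "miou", "re", "pr", "sp")])))

  pooled <- list(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in seq_along(bin)) {
    cc <- confusion_counts(truths[[i]], bin[[i]])
    pooled <- Map(`+`, pooled, cc)
  }
  rt <- rate_metrics(pooled)
  dsc_g <- if (2 * pooled$TP + pooled$FP + pooled$FN == 0) 1 else
    2 * pooled$TP / (2 * pooled$TP + pooled$FP + pooled$FN)
  miou_g <- if (pooled$TP + pooled$FP + pooled$FN == 0) 1 else
    pooled$TP / (pooled$TP + pooled$FP + pooled$FN)
  global <- c(dsc = dsc_g, f1 = rt$f1, miou = miou_g, re = rt$re,
              pr = rt$pr, sp = rt$sp)

  out <- rbind(data.frame(aggregation = "per_image_mean",
                          t(per_mean)),
               data.frame(aggregation = "global_pixels",
                          t(unlist(global))))
  structure(out, class = c("tmd_metrics_report", "data.frame"),
            n_images = length(bin), threshold = threshold)
}

#' @export
print.tmd_metrics_report <- function(x, ...) {
  cat(sprintf("Metrics over %d image(s), threshold %.2f (%%):\n",
              attr(x, "n_images"), attr(x, "threshold")))
  shown <- as.data.frame(x)
  num <- vapply(shown, is.numeric, logical(1))
  shown[num] <- lapply(shown[num], function(v) sprintf("%.2f", 100 * v))
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' Percentages to two decimals, keyed metric x aggregation.
#'
#' @param report an [evaluate_set()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "tmd_metrics_report"))
  out <- lapply(seq_len(nrow(report)), function(i) {
    row <- report[i, c("dsc", "f1", "miou", "re", "pr", "sp")]
    lapply(row, function(v) round(100 * v, 2))
  })
  names(out) <- report$aggregation
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
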