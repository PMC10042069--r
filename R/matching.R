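#' Match detections to ground truth by IoU
#'
#' Defines the correctness label `z` that the calibration stack consumes.
#' Detections below `conf_thresh` are discarded first. The survivors are
#' processed in order of descending confidence (ties broken by input order)
#' and each is greedily assigned the not-yet-matched ground-truth box of the
#' same class, in the same image, with the highest IoU at or above
#' `iou_thresh` (IoU ties go to the lowest ground-truth index). Each ground
#' truth can be matched at most once, so duplicate detections of the same
#' region count as false positives. Unmatched detections are FP; unmatched
#' ground truths are FN.
#'
#' @param detections detections data frame (see [detections_frame()]).
#' @param ground_truth ground-truth data frame
#'   (see [ground_truth_frame()]).
#' @param iou_thresh minimum IoU for a detection to count as correct
#'   (default 0.5).
#' @param conf_thresh confidence cutoff below which detections are ignored
#'   (default 0.4, the operating point used for reporting detector
#'   precision/recall).
#' @return A list of class `match_result` with elements:
#'   \describe{
#'     \item{matches}{data frame over surviving detections:
#'       `det_index` (row in `detections`), `image_id`, `class_id`,
#'       `confidence`, `gt_index` (row in `ground_truth`, `NA` if
#'       unmatched), `iou` and `z`.}
#'     \item{metrics}{a [detection_metrics()] object with TP/FP/FN counts
#'       and precision/recall/F1.}
#'   }
#' @export
match_detections <- function(detections, ground_truth, iou_thresh = 0.5,
                             conf_thresh = 0.4) {
  check_fraction(iou_thresh, "iou_thresh", closed = TRUE)
  check_fraction(conf_thresh, "conf_thresh", closed = TRUE)
  validate_boxes(detections, "detection box")
  validate_boxes(ground_truth, "ground-truth box")

  surv <- which(detections$confidence >= conf_thresh)
  n_surv <- length(surv)
  matches <- data.frame(
    det_index = surv,
    image_id = detections$image_id[surv],
    class_id = detections$class_id[surv],
    confidence = detections$confidence[surv],
    gt_index = rep(NA_integer_, n_surv),
    iou = rep(0, n_surv),
    z = rep(0L, n_surv))

  # matching is per (image, class); group keys shared by both tables
  det_key <- paste(matches$image_id, matches$class_id, sep = "\r")
  gt_key <- paste(ground_truth$image_id, ground_truth$class_id, sep = "\r")

  for (key in unique(det_key)) {
    di <- which(det_key == key)           # rows of `matches`
    gi <- which(gt_key == key)            # rows of `ground_truth`
    if (length(gi) == 0L) next
    im <- iou_matrix(detections[matches$det_index[di], , drop = FALSE],
                     ground_truth[gi, , drop = FALSE])
    gt_taken <- rep(FALSE, length(gi))
    # stable descending-confidence order: order() is stable, so confidence
    # ties fall back to input order
    for (d in order(-matches$confidence[di])) {
      cand <- which(!gt_taken & im[d, ] >= iou_thresh)
      if (length(cand) == 0L) next
      best <- cand[which.max(im[d, cand])]  # which.max -> lowest index on ties
      gt_taken[best] <- TRUE
      matches$gt_index[di[d]] <- gi[best]
      matches$iou[di[d]] <- im[d, best]
      matches$z[di[d]] <- 1L
    }
  }

  tp <- sum(matches$z)
  metrics <- detection_metrics(tp = tp, fp = n_surv - tp,
                               fn = nrow(ground_truth) - tp)
  structure(list(matches = matches, metrics = metrics),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d detection(s) matched against ground truth\n",
              nrow(x$matches)))
  print(x$metrics)
  invisible(x)
}

#' Detection metrics from TP/FP/FN counts
#'
#' precision = TP / (TP + FP), recall = TP / (TP + FN) and
#' f1 = 2 * precision * recall / (precision + recall). Degenerate 0/0 cases
#' are defined conservatively as 0: precision is 0 when there are no
#' detections, recall is 0 when there are no ground truths, and f1 is 0
#' when precision + recall = 0.
#'
#' @param tp,fp,fn nonnegative integer counts of true positives, false
#'   positives and false negatives.
#' @return A list of class `detection_metrics` with fields `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @examples
#' detection_metrics(3, 1, 2)
#' @export
detection_metrics <- function(tp, fp, fn) {
  tp <- check_count(tp, "tp")
  fp <- check_count(fp, "fp")
  fn <- check_count(fn, "fn")
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | precision %.4f  recall %.4f  f1 %.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Build calibration records from a matching result
#'
#' Converts matched detections into the record rows consumed by [ece()] and
#' [fit_dependent_logistic()]: confidence, the box center normalized by the
#' image dimensions, and `z` from the match. Missed ground truths (FN) carry
#' no confidence and never become records; calibration operates on
#' predictions only.
#'
#' @param detections the detections data frame given to
#'   [match_detections()].
#' @param match a `match_result` from [match_detections()].
#' @param image_sizes data frame with columns `image_id`, `width`, `height`
#'   covering every image that has a surviving detection.
#' @return A calibration-record data frame (see [calibration_records()]).
#' @export
records_from_matches <- function(detections, match, image_sizes) {
  stopifnot(inherits(match, "match_result"))
  need <- c("image_id", "width", "height")
  if (!all(need %in% names(image_sizes))) {
    stop("`image_sizes` needs columns image_id, width, height",
         call. = FALSE)
  }
  m <- match$matches
  idx <- base::match(m$image_id, image_sizes$image_id)
  if (anyNA(idx)) {
    stop(sprintf("no image size for image_id '%s'",
                 m$image_id[which(is.na(idx))[1L]]), call. = FALSE)
  }
  centers <- box_centers(detections[m$det_index, , drop = FALSE])
  calibration_records(
    image_id = m$image_id,
    class_id = m$class_id,
    confidence = m$confidence,
    cx_norm = centers[, "cx"] / image_sizes$width[idx],
    cy_norm = centers[, "cy"] / image_sizes$height[idx],
    z = m$z,
    calibrated_confidence =
      detections$calibrated_confidence[m$det_index] %||% NA_real_)
}
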