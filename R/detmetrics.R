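# Detection evaluation: greedy IoU matching, precision/recall/F1, and
# COCO-style 101-point interpolated average precision.
#
# Record schemas (plain data frames):
#   detections   : image_id, class_id, score, cx, cy, w, h
#   ground truth : image_id, class_id, cx, cy, w, h

#' Construct detection / ground-truth record tables
#'
#' Thin validating constructors around the delimited record schemas the
#' evaluator consumes.  Scores must lie in \[0, 1\]; boxes must be
#' valid.
#'
#' @param image_id,class_id Identifier vectors.
#' @param score Confidence scores in \[0, 1\].
#' @param cx,cy,w,h Box coordinates (center/size, pixels).
#' @return A data frame in the corresponding schema.
#' @export
detection_records <- function(image_id, class_id, score, cx, cy, w, h) {
  b <- boxes(cx, cy, w, h)
  score <- as.numeric(score)
  if (any(score < 0 | score > 1)) stop_usage("scores must lie in [0, 1]")
  data.frame(image_id = as.character(image_id), class_id = as.character(class_id),
             score = score, b, stringsAsFactors = FALSE)
}

#' @rdname detection_records
#' @export
ground_truth_records <- function(image_id, class_id, cx, cy, w, h) {
  b <- boxes(cx, cy, w, h)
  data.frame(image_id = as.character(image_id), class_id = as.character(class_id),
             b, stringsAsFactors = FALSE)
}

# Deterministic detection ordering: score descending, then a
# content-based key so permuting record order cannot change any metric.
det_order <- function(d) {
  order(-d$score, d$image_id, d$class_id, d$cx, d$cy, d$w, d$h)
}

#' Greedy IoU matching of detections to ground truth
#'
#' Within each (image, class) group, detections are visited in order of
#' descending score and matched to the not-yet-matched ground-truth box
#' of highest IoU, provided that IoU reaches `iou_threshold`; each
#' ground-truth box matches at most once, and IoU ties go to the lowest
#' ground-truth index.  Unmatched detections are false positives;
#' unmatched ground truths are false negatives.
#'
#' @param dets Detection records (see [detection_records()]).
#' @param gts Ground-truth records (see [ground_truth_records()]).
#' @param iou_threshold IoU required for a match, in \[0, 1\].
#' @return A list with `dets` (the detections plus logical `tp` and
#'   integer `matched_gt` row index into `gts`) and `gts` (plus logical
#'   `matched`).
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  dets$.row <- seq_len(nrow(dets))
  gts$.row <- if (nrow(gts)) seq_len(nrow(gts)) else integer(0)
  tp <- logical(nrow(dets))
  matched_gt <- rep(NA_integer_, nrow(dets))
  gt_matched <- logical(nrow(gts))
  if (nrow(dets)) {
    keys <- unique(dets[c("image_id", "class_id")])
    for (kk in seq_len(nrow(keys))) {
      di <- which(dets$image_id == keys$image_id[kk] &
                  dets$class_id == keys$class_id[kk])
      gi <- which(gts$image_id == keys$image_id[kk] &
                  gts$class_id == keys$class_id[kk])
      di <- di[det_order(dets[di, , drop = FALSE])]
      taken <- logical(length(gi))
      for (d in di) {
        if (!length(gi)) next
        ious <- box_iou(dets[rep(d, length(gi)), c("cx", "cy", "w", "h")],
                        gts[gi, c("cx", "cy", "w", "h")])
        ious[taken] <- -1
        best <- which(ious == max(ious))[1L]   # tie -> lowest gt index
        if (ious[best] >= iou_threshold && ious[best] >= 0) {
          tp[d] <- TRUE
          matched_gt[d] <- gi[best]
          taken[best] <- TRUE
        }
      }
      gt_matched[gi[taken]] <- TRUE
    }
  }
  dets$tp <- tp
  dets$matched_gt <- matched_gt
  gts$matched <- gt_matched
  dets$.row <- NULL; gts$.row <- NULL
  list(dets = dets, gts = gts)
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F1 = 2PR / (P + R)`, with the 0/0 cases defined as 0 so that
#' degenerate record sets never propagate NaN.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A list with elements `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1)
}

#' Average precision for one class at one IoU threshold
#'
#' Builds the precision-recall curve by sweeping the score ranking of
#' all detections of the class (greedy matching is prefix-consistent:
#' the decisions for high-score detections do not depend on lower-score
#' ones) and integrates it with the 101-point interpolation (precision
#' envelope sampled at recalls 0.00, 0.01, ..., 1.00).
#'
#' @inheritParams match_detections
#' @param class_id The class to evaluate.
#' @return AP in \[0, 1\], or `NA` if the class has no ground truth
#'   (AP is undefined, not 0).
#' @export
average_precision <- function(dets, gts, class_id, iou_threshold = 0.5) {
  gts_c <- gts[gts$class_id == class_id, , drop = FALSE]
  npos <- nrow(gts_c)
  if (npos == 0L) return(NA_real_)
  dets_c <- dets[dets$class_id == class_id, , drop = FALSE]
  if (nrow(dets_c) == 0L) return(0)
  m <- match_detections(dets_c, gts_c, iou_threshold)$dets
  m <- m[det_order(m), , drop = FALSE]
  cum_tp <- cumsum(m$tp)
  cum_fp <- cumsum(!m$tp)
  recall <- cum_tp / npos
  precision <- cum_tp / (cum_tp + cum_fp)
  grid <- seq(0, 1, by = 0.01)
  interp <- vapply(grid, function(r) {
    keep <- recall >= r - 1e-12
    if (any(keep)) max(precision[keep]) else 0
  }, numeric(1))
  mean(interp)
}

#' Mean average precision over classes and IoU thresholds
#'
#' `mAP` is the mean of per-class AP values; with several thresholds
#' (e.g. `seq(0.5, 0.95, by = 0.05)` for mAP0.5-0.95) the mean runs
#' over classes and thresholds.  Classes present only in the detections
#' (no ground truth) are excluded, since their AP is undefined.
#'
#' @inheritParams match_detections
#' @param thresholds IoU thresholds to average over.
#' @return A list with `map` (the scalar mean) and `per_class` (a data
#'   frame of class, threshold, ap).
#' @export
mean_ap <- function(dets, gts, thresholds = 0.5) {
  classes <- sort(unique(gts$class_id))
  if (length(classes) == 0L) stop_usage("ground truth contains no classes")
  tab <- expand.grid(class_id = classes, iou_threshold = thresholds,
                     stringsAsFactors = FALSE)
  tab$ap <- mapply(function(cl, th) average_precision(dets, gts, cl, th),
                   tab$class_id, tab$iou_threshold)
  list(map = mean(tab$ap, na.rm = TRUE), per_class = tab)
}

#' Evaluation summary at a confidence cut
#'
#' Per-class AP at IoU 0.5, mAP0.5, mAP0.5-0.95, and precision, recall
#' and F1 computed from the detections whose score reaches
#' `score_threshold` (default 0.55) matched at IoU 0.5.
#'
#' @inheritParams match_detections
#' @param score_threshold Confidence cut applied before counting
#'   TP/FP/FN.
#' @return A list with `per_class_ap`, `map50`, `map5095`,
#'   `precision`, `recall`, `f1`.
#' @export
evaluate_detections <- function(dets, gts, score_threshold = 0.55) {
  m50 <- mean_ap(dets, gts, 0.5)
  m5095 <- mean_ap(dets, gts, seq(0.5, 0.95, by = 0.05))
  kept <- dets[dets$score >= score_threshold, , drop = FALSE]
  mm <- match_detections(kept, gts, 0.5)
  tp <- sum(mm$dets$tp); fp <- sum(!mm$dets$tp); fn <- sum(!mm$gts$matched)
  prf <- precision_recall_f1(tp, fp, fn)
  list(per_class_ap = m50$per_class, map50 = m50$map, map5095 = m5095$map,
       precision = prf$precision, recall = prf$recall, f1 = prf$f1)
}

#' Read detection / ground-truth records from delimited text
#'
#' Whitespace-separated, one record per line:
#' `image_id class_id score cx cy w h` for detections and
#' `image_id class_id cx cy w h` for ground truth; `#` starts a
#' comment.
#'
#' @param path File path.
#' @return A record data frame.
#' @export
read_detections <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("image_id", "class_id", "score",
                                        "cx", "cy", "w", "h"),
                          colClasses = c("character", "character", rep("numeric", 5)))
  detection_records(df$image_id, df$class_id, df$score, df$cx, df$cy, df$w, df$h)
}

#' @rdname read_detections
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("image_id", "class_id",
                                        "cx", "cy", "w", "h"),
                          colClasses = c("character", "character", rep("numeric", 4)))
  ground_truth_records(df$image_id, df$class_id, df$cx, df$cy, df$w, df$h)
}
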