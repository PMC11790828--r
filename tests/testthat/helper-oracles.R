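# Shared fixtures and independent oracles.

# Random valid boxes: centers in [-5, 5], sides in [0.5, 6].
random_boxes <- function(n) {
  boxes(runif(n, -5, 5), runif(n, -5, 5), runif(n, 0.5, 6), runif(n, 0.5, 6))
}

# Brute-force sliding-window max pooling: O(k^2 H W) double loop.
max_pool_oracle <- function(x, kernel) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  p <- (kernel - 1) / 2
  out <- array(NA_real_, d)
  for (ci in seq_len(C)) {
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        ii <- max(1, i - p):min(H, i + p)
        jj <- max(1, j - p):min(W, j + p)
        out[ci, i, j] <- max(x[ci, ii, jj])
      }
    }
  }
  out
}

# Exhaustive threshold-enumeration AP oracle: re-runs the matching from
# scratch at every distinct score cut, collects (recall, precision)
# points, and integrates the precision envelope on the 101-point grid.
# Assumes tie-free scores (see random record generator below).
ap_oracle <- function(dets, gts, class_id, iou_threshold = 0.5) {
  gts_c <- gts[gts$class_id == class_id, , drop = FALSE]
  npos <- nrow(gts_c)
  if (npos == 0L) return(NA_real_)
  dets_c <- dets[dets$class_id == class_id, , drop = FALSE]
  if (nrow(dets_c) == 0L) return(0)
  pts_r <- numeric(0); pts_p <- numeric(0)
  for (t in sort(unique(dets_c$score), decreasing = TRUE)) {
    sub <- dets_c[dets_c$score >= t, , drop = FALSE]
    m <- match_detections(sub, gts_c, iou_threshold)
    tp <- sum(m$dets$tp); fp <- sum(!m$dets$tp)
    pts_r <- c(pts_r, tp / npos)
    pts_p <- c(pts_p, tp / (tp + fp))
  }
  grid <- seq(0, 1, by = 0.01)
  mean(vapply(grid, function(r) {
    keep <- pts_r >= r - 1e-12
    if (any(keep)) max(pts_p[keep]) else 0
  }, numeric(1)))
}

# Random detection/ground-truth record sets with tie-free scores:
# detections are jittered copies of random ground-truth boxes with
# occasional class confusion.
random_record_set <- function(n_images = 2, n_classes = 2, n_gt = 6, n_det = 10) {
  imgs <- sprintf("im%d", seq_len(n_images))
  cls <- sprintf("c%d", seq_len(n_classes))
  gts <- ground_truth_records(
    sample(imgs, n_gt, replace = TRUE), sample(cls, n_gt, replace = TRUE),
    runif(n_gt, 5, 55), runif(n_gt, 5, 55), runif(n_gt, 4, 14), runif(n_gt, 4, 14))
  base <- gts[sample.int(n_gt, n_det, replace = TRUE), , drop = FALSE]
  dets <- detection_records(
    base$image_id, sample(cls, n_det, replace = TRUE), runif(n_det),
    base$cx + rnorm(n_det, 0, 3), base$cy + rnorm(n_det, 0, 3),
    base$w * exp(rnorm(n_det, 0, 0.2)), base$h * exp(rnorm(n_det, 0, 0.2)))
  list(dets = dets, gts = gts, classes = cls)
}
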