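# The iSD-IoU bounding-box regression loss and the IoU/DIoU/CIoU
# reference losses it is compared against.
#
#   L = (1 - IoU^in) + Delta + Omega
#
# IoU^in is the IoU of auxiliary "inner" boxes (same centers, sides
# scaled by `ratio`); Delta is an exponential penalty on the center
# offset normalized by the enclosing-box extents, weighted per axis by
# ground-truth-shape weights; Omega is an exponential penalty on the
# relative width/height mismatch raised to the exponent `theta`.

#' Hyperparameter configuration for the iSD-IoU loss
#'
#' Validates the admissible ranges of the four scalar hyperparameters:
#' `ratio` (inner-box side scaling) in \[0.5, 1.5\], `k` (distance-loss
#' weight) in (0, 1\], `theta` (shape-loss exponent) in \[2, 6\], and
#' `s` (shape-weight scale exponent) >= 0.  Out-of-range values are
#' rejected with a config error naming the offending key and bound.
#'
#' `shape_weight_pairing` selects how the ground-truth shape weights
#' attach to the width/height mismatch terms: `"crossed"` (the printed
#' form: the width term is weighted by the vertical weight `h1` and the
#' height term by the horizontal weight `w1`) or `"direct"` (w-with-w1,
#' h-with-h1).  The crossed form is the default.
#'
#' @param ratio Inner-box scaling factor, in \[0.5, 1.5\].  At
#'   `ratio = 1` the inner IoU reduces to the plain IoU.
#' @param k Distance-loss weight, in (0, 1\].
#' @param theta Shape-loss exponent, in \[2, 6\].
#' @param s Scale exponent of the shape weights, >= 0.  `s = 0` makes
#'   both weights 1.
#' @param shape_weight_pairing `"crossed"` or `"direct"` (see Details).
#' @return A list of class `"isd_config"`.
#' @export
isd_config <- function(ratio = 1.0, k = 0.5, theta = 4, s = 1.0,
                       shape_weight_pairing = c("crossed", "direct")) {
  shape_weight_pairing <- match.arg(shape_weight_pairing)
  check_num <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop_config(sprintf("'%s' must be a single finite number", nm))
    as.numeric(x)
  }
  ratio <- check_num(ratio, "ratio"); k <- check_num(k, "k")
  theta <- check_num(theta, "theta"); s <- check_num(s, "s")
  if (ratio < 0.5 || ratio > 1.5)
    stop_config(sprintf("'ratio' = %g is outside the admissible range [0.5, 1.5]", ratio))
  if (k <= 0 || k > 1)
    stop_config(sprintf("'k' = %g is outside the admissible range (0, 1]", k))
  if (theta < 2 || theta > 6)
    stop_config(sprintf("'theta' = %g is outside the admissible range [2, 6]", theta))
  if (s < 0)
    stop_config(sprintf("'s' = %g must be >= 0", s))
  structure(list(ratio = ratio, k = k, theta = theta, s = s,
                 shape_weight_pairing = shape_weight_pairing),
            class = "isd_config")
}

#' Inner-box IoU
#'
#' IoU of auxiliary boxes that share the input boxes' centers with all
#' sides scaled by `ratio`.  Intersection extents are clamped at zero,
#' so the result lies in \[0, 1\]; at `ratio = 1` it equals the plain
#' IoU exactly.
#'
#' @inheritParams box_iou
#' @param ratio Inner-box scaling factor in \[0.5, 1.5\].
#' @return Numeric vector in \[0, 1\].
#' @examples
#' inner_iou(boxes(1, 0, 4, 4), boxes(0, 0, 4, 4), ratio = 0.5)  # 1/3
#' @export
inner_iou <- function(pred, gt, ratio = 1.0) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio < 0.5 || ratio > 1.5)
    stop_config(sprintf("'ratio' = %g is outside the admissible range [0.5, 1.5]", ratio))
  p <- box_pair(pred, gt)
  # inner corners: same centers, sides scaled by ratio
  al <- p$pred$cx - p$pred$w * ratio / 2; ar <- p$pred$cx + p$pred$w * ratio / 2
  at <- p$pred$cy - p$pred$h * ratio / 2; ab <- p$pred$cy + p$pred$h * ratio / 2
  bl <- p$gt$cx - p$gt$w * ratio / 2;  br <- p$gt$cx + p$gt$w * ratio / 2
  bt <- p$gt$cy - p$gt$h * ratio / 2;  bb <- p$gt$cy + p$gt$h * ratio / 2
  inter <- pmax(0, pmin(br, ar) - pmax(bl, al)) *
           pmax(0, pmin(bb, ab) - pmax(bt, at))
  union <- (p$gt$w * p$gt$h) * ratio^2 + (p$pred$w * p$pred$h) * ratio^2 - inter
  inter / union
}

#' Ground-truth shape weights
#'
#' Per-axis weights derived from the ground-truth box shape,
#' `w1 = 2 (w^gt)^s / ((w^gt)^s + (h^gt)^s)` and symmetrically for
#' `h1`; they always sum to 2, and a square ground truth (or `s = 0`)
#' gives `w1 = h1 = 1`.
#'
#' @param gt Ground-truth boxes table.
#' @param s Scale exponent, >= 0.
#' @return A data frame with columns `w1`, `h1`.
#' @export
shape_weights <- function(gt, s = 1.0) {
  if (!is.numeric(s) || length(s) != 1L || s < 0)
    stop_config(sprintf("'s' = %g must be >= 0", s))
  gt <- as_boxes(gt)
  ws <- gt$w^s; hs <- gt$h^s
  data.frame(w1 = 2 * ws / (ws + hs), h1 = 2 * hs / (ws + hs))
}

#' Distance term of the iSD-IoU loss
#'
#' Exponential penalty on the center offset between predicted and
#' ground-truth boxes, normalized per axis by the enclosing-box width
#' and height and weighted by the ground-truth shape weights:
#' `Delta = k * sum_t (1 - exp(-rho_t))` with
#' `rho_x = w1 ((cx - cx^gt) / wc)^2` and
#' `rho_y = h1 ((cy - cy^gt) / hc)^2`.  Bounded by `2 k`; zero for
#' concentric boxes; invariant under joint translation and scaling.
#'
#' @inheritParams box_iou
#' @param cfg An [isd_config()].
#' @return Numeric vector, in \[0, 2k\].
#' @export
distance_term <- function(pred, gt, cfg = isd_config()) {
  stopifnot(inherits(cfg, "isd_config"))
  p <- box_pair(pred, gt)
  enc <- box_enclosure(p$pred, p$gt)
  sw <- shape_weights(p$gt, cfg$s)
  rho_x <- sw$w1 * ((p$pred$cx - p$gt$cx) / enc$wc)^2
  rho_y <- sw$h1 * ((p$pred$cy - p$gt$cy) / enc$hc)^2
  cfg$k * ((1 - exp(-rho_x)) + (1 - exp(-rho_y)))
}

#' Shape term of the iSD-IoU loss
#'
#' Exponential penalty on relative width/height mismatch,
#' `Omega = 1/2 * sum_t (1 - exp(-w_t))^theta`, where
#' `w_w = h1 |w - w^gt| / max(w, w^gt)` and
#' `w_h = w1 |h - h^gt| / max(h, h^gt)` under the default `"crossed"`
#' weight pairing (the `"direct"` pairing swaps the weights).  Zero for
#' identically shaped boxes at any positions; bounded by 1.
#'
#' @inheritParams distance_term
#' @return Numeric vector in \[0, 1\].
#' @export
shape_term <- function(pred, gt, cfg = isd_config()) {
  stopifnot(inherits(cfg, "isd_config"))
  p <- box_pair(pred, gt)
  sw <- shape_weights(p$gt, cfg$s)
  rel_w <- abs(p$pred$w - p$gt$w) / pmax(p$pred$w, p$gt$w)
  rel_h <- abs(p$pred$h - p$gt$h) / pmax(p$pred$h, p$gt$h)
  if (cfg$shape_weight_pairing == "crossed") {
    ww <- sw$h1 * rel_w; wh <- sw$w1 * rel_h
  } else {
    ww <- sw$w1 * rel_w; wh <- sw$h1 * rel_h
  }
  0.5 * ((1 - exp(-ww))^cfg$theta + (1 - exp(-wh))^cfg$theta)
}

#' The iSD-IoU loss with its per-pair decomposition
#'
#' Computes, per box pair, the inner IoU, the distance term, the shape
#' term, and the total `(1 - iou_in) + delta + omega`.  The total is
#' exactly the sum of the reported components (no hidden reweighting),
#' vanishes iff the boxes are identical, and is invariant under joint
#' translation and joint positive scaling of both boxes.
#'
#' @inheritParams distance_term
#' @return A data frame with columns `iou_in`, `delta`, `omega`,
#'   `total`.
#' @examples
#' isd_loss(boxes(1, 0, 4, 4), boxes(0, 0, 4, 4),
#'          isd_config(ratio = 1, k = 0.5, theta = 4, s = 1))
#' @export
isd_loss <- function(pred, gt, cfg = isd_config()) {
  stopifnot(inherits(cfg, "isd_config"))
  p <- box_pair(pred, gt)
  iou_in <- inner_iou(p$pred, p$gt, cfg$ratio)
  delta <- distance_term(p$pred, p$gt, cfg)
  omega <- shape_term(p$pred, p$gt, cfg)
  data.frame(iou_in = iou_in, delta = delta, omega = omega,
             total = (1 - iou_in) + delta + omega)
}

#' Reference bounding-box regression losses
#'
#' The standard comparison baselines: `L_IoU = 1 - IoU`;
#' `L_DIoU = 1 - IoU + d^2 / c^2` with `d` the center distance and `c`
#' the enclosing-box diagonal; `L_CIoU = L_DIoU + alpha * v` with
#' `v = (4/pi^2)(atan(w^gt/h^gt) - atan(w/h))^2` and
#' `alpha = v / ((1 - IoU) + v)`.
#'
#' @inheritParams box_iou
#' @param which One of `"iou"`, `"diou"`, `"ciou"`.
#' @return Numeric vector of non-negative loss values.
#' @export
reference_loss <- function(pred, gt, which = c("iou", "diou", "ciou")) {
  if (length(which) == 1L && !which %in% c("iou", "diou", "ciou"))
    stop_usage(sprintf("unknown loss name '%s' (expected iou, diou or ciou)", which))
  which <- match.arg(which)
  p <- box_pair(pred, gt)
  iou <- box_iou(p$pred, p$gt)
  if (which == "iou") return(1 - iou)
  enc <- box_enclosure(p$pred, p$gt)
  d2 <- (p$pred$cx - p$gt$cx)^2 + (p$pred$cy - p$gt$cy)^2
  diou <- 1 - iou + d2 / enc$diag^2
  if (which == "diou") return(diou)
  v <- (4 / pi^2) * (atan(p$gt$w / p$gt$h) - atan(p$pred$w / p$pred$h))^2
  alpha <- ifelse(v > 0, v / ((1 - iou) + v), 0)
  diou + alpha * v
}
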