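# Axis-aligned boxes in center/size parametrization.
#
# Coordinate convention: continuous pixel coordinates, x increases
# rightward, y increases downward.  Boxes are stored as (cx, cy, w, h)
# with w > 0, h > 0; the corner view (x1, y1, x2, y2) is derived as
# x1 = cx - w/2, x2 = cx + w/2, y1 = cy - h/2, y2 = cy + h/2.

stop_box <- function(msg) {
  stop(errorCondition(msg, class = c("isdiou_box_error", "isdiou_error", "error")))
}

stop_usage <- function(msg) {
  stop(errorCondition(msg, class = c("isdiou_usage_error", "isdiou_error", "error")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("isdiou_config_error", "isdiou_error", "error")))
}

#' Construct a table of axis-aligned boxes
#'
#' Boxes are the unit of all loss computations in the package.  They are
#' stored in center/size parametrization: center `(cx, cy)` plus width
#' `w` and height `h`, all in (continuous) pixels.  Degenerate boxes
#' (`w <= 0` or `h <= 0`) are rejected at construction: every downstream
#' loss formula divides by widths, heights, or enclosing extents.
#'
#' @param cx,cy Numeric vectors of box center coordinates (pixels).
#' @param w,h Numeric vectors of box widths/heights (pixels, strictly
#'   positive).  Arguments are recycled to a common length.
#' @return A `data.frame` of class `"boxes"` with columns
#'   `cx`, `cy`, `w`, `h`.
#' @examples
#' b <- boxes(cx = c(0, 1), cy = 0, w = 4, h = 4)
#' box_convert(b, to = "corner")
#' @export
boxes <- function(cx, cy, w, h) {
  df <- data.frame(cx = as.numeric(cx), cy = as.numeric(cy),
                   w = as.numeric(w), h = as.numeric(h))
  validate_boxes(df)
}

#' Coerce an object to a boxes table
#'
#' @param x A `data.frame` or numeric matrix with four columns.  In
#'   `"center"` convention the columns are `cx, cy, w, h`; in
#'   `"corner"` convention they are `x1, y1, x2, y2` (left, top, right,
#'   bottom).
#' @param convention Which view the columns of `x` are in.
#' @return A validated `boxes` data frame (center/size view).
#' @export
as_boxes <- function(x, convention = c("center", "corner")) {
  convention <- match.arg(convention)
  if (inherits(x, "boxes") && convention == "center") return(x)
  if (is.matrix(x)) x <- as.data.frame(x)
  if (!is.data.frame(x) || ncol(x) < 4L)
    stop_usage("boxes require four numeric columns")
  if (convention == "center") {
    cols <- if (all(c("cx", "cy", "w", "h") %in% names(x)))
      c("cx", "cy", "w", "h") else names(x)[1:4]
    boxes(x[[cols[1]]], x[[cols[2]]], x[[cols[3]]], x[[cols[4]]])
  } else {
    cols <- if (all(c("x1", "y1", "x2", "y2") %in% names(x)))
      c("x1", "y1", "x2", "y2") else names(x)[1:4]
    x1 <- as.numeric(x[[cols[1]]]); y1 <- as.numeric(x[[cols[2]]])
    x2 <- as.numeric(x[[cols[3]]]); y2 <- as.numeric(x[[cols[4]]])
    boxes((x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1)
  }
}

validate_boxes <- function(df) {
  if (!all(vapply(df[c("cx", "cy", "w", "h")], is.numeric, logical(1))))
    stop_box("box coordinates must be numeric")
  if (any(!is.finite(as.matrix(df[c("cx", "cy", "w", "h")]))))
    stop_box("box coordinates must be finite")
  if (any(df$w <= 0) || any(df$h <= 0))
    stop_box("invalid box: width and height must be strictly positive")
  class(df) <- c("boxes", "data.frame")
  df
}

#' Convert boxes between center/size and corner views
#'
#' The two views are mutually consistent and the round trip is exact to
#' floating precision.
#'
#' @param b A boxes table (or anything `as_boxes()` accepts).
#' @param to Target view: `"corner"` yields columns `x1, y1, x2, y2`
#'   (left, top, right, bottom), `"center"` yields a `boxes` table.
#' @return A data frame in the requested view.
#' @export
box_convert <- function(b, to = c("corner", "center")) {
  to <- match.arg(to)
  b <- as_boxes(b)
  if (to == "center") return(b)
  data.frame(x1 = b$cx - b$w / 2, y1 = b$cy - b$h / 2,
             x2 = b$cx + b$w / 2, y2 = b$cy + b$h / 2)
}

# Align a predicted-box table and a ground-truth table row-for-row,
# recycling a single-row table against a longer one.
box_pair <- function(pred, gt) {
  pred <- as_boxes(pred); gt <- as_boxes(gt)
  np <- nrow(pred); ng <- nrow(gt)
  if (np == ng) return(list(pred = pred, gt = gt))
  if (np == 1L) return(list(pred = pred[rep(1L, ng), , drop = FALSE], gt = gt))
  if (ng == 1L) return(list(pred = pred, gt = gt[rep(1L, np), , drop = FALSE]))
  stop_usage(sprintf("box tables have incompatible row counts (%d vs %d)", np, ng))
}

#' Intersection over union of paired boxes
#'
#' Overlap extents are clamped at zero before multiplying, so disjoint
#' boxes score exactly 0 and the result always lies in \[0, 1\].
#'
#' @param pred,gt Boxes tables, matched row-for-row (either may have a
#'   single row, which is recycled).
#' @return Numeric vector of IoU values in \[0, 1\].
#' @examples
#' box_iou(boxes(1, 0, 4, 4), boxes(0, 0, 4, 4))  # 12/20 = 0.6
#' @export
box_iou <- function(pred, gt) {
  p <- box_pair(pred, gt)
  a <- box_convert(p$pred, "corner"); b <- box_convert(p$gt, "corner")
  iw <- pmax(0, pmin(a$x2, b$x2) - pmax(a$x1, b$x1))
  ih <- pmax(0, pmin(a$y2, b$y2) - pmax(a$y1, b$y1))
  inter <- iw * ih
  union <- p$pred$w * p$pred$h + p$gt$w * p$gt$h - inter
  inter / union
}

#' Minimum enclosing box of paired boxes
#'
#' Returns, per pair, the width `wc` and height `hc` of the smallest
#' axis-aligned box covering both input boxes, plus the diagonal
#' `diag = sqrt(wc^2 + hc^2)`.  `wc`/`hc` normalize the distance penalty
#' of the iSD-IoU loss; `diag` is the `c` of the DIoU/CIoU penalties.
#'
#' @inheritParams box_iou
#' @return A data frame with columns `wc`, `hc`, `diag`.
#' @export
box_enclosure <- function(pred, gt) {
  p <- box_pair(pred, gt)
  a <- box_convert(p$pred, "corner"); b <- box_convert(p$gt, "corner")
  wc <- pmax(a$x2, b$x2) - pmin(a$x1, b$x1)
  hc <- pmax(a$y2, b$y2) - pmin(a$y1, b$y1)
  data.frame(wc = wc, hc = hc, diag = sqrt(wc^2 + hc^2))
}

#' Read/write box tables as plain delimited text
#'
#' One box per line, whitespace-separated `cx cy w h`; lines starting
#' with `#` are ignored.  This is the schema the command-line interface
#' consumes.
#'
#' @param path File path.
#' @return `read_boxes()` returns a `boxes` table.
#' @export
read_boxes <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("cx", "cy", "w", "h"))
  as_boxes(df)
}

#' @param b A boxes table.
#' @rdname read_boxes
#' @export
write_boxes <- function(b, path) {
  b <- as_boxes(b)
  utils::write.table(b, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
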