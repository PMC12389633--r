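# Box utilities. All boxes are 0-based half-open (x1, y1, x2, y2) matrices
# in pixel units: width = x2 - x1, height = y2 - y1. VOC's 1-based
# inclusive corners are converted at the annotation boundary only.

#' Intersection-over-union between two box sets
#'
#' @param a n x 4 matrix, `b` m x 4 matrix, both 0-based half-open
#' @return n x m IoU matrix
#' @export
box_iou <- function(a, b) {
  a <- matrix(a, ncol = 4)
  b <- matrix(b, ncol = 4)
  n <- nrow(a)
  m <- nrow(b)
  ix1 <- outer(a[, 1], b[, 1], pmax)
  iy1 <- outer(a[, 2], b[, 2], pmax)
  ix2 <- outer(a[, 3], b[, 3], pmin)
  iy2 <- outer(a[, 4], b[, 4], pmin)
  iw <- pmax(ix2 - ix1, 0)
  ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  area_a <- pmax(a[, 3] - a[, 1], 0) * pmax(a[, 4] - a[, 2], 0)
  area_b <- pmax(b[, 3] - b[, 1], 0) * pmax(b[, 4] - b[, 2], 0)
  un <- outer(area_a, area_b, `+`) - inter
  out <- inter / pmax(un, 1e-12)
  matrix(out, n, m)
}

#' Greedy non-maximum suppression
#'
#' Keeps the highest-scoring box and discards any remaining box whose IoU
#' with a kept box exceeds `iou_thr`; repeats on the survivors.
#'
#' @param boxes n x 4 matrix
#' @param scores length-n scores
#' @param iou_thr suppression threshold in (0, 1)
#' @return indices of kept boxes, in decreasing score order
#' @export
nms <- function(boxes, scores, iou_thr = 0.7) {
  boxes <- matrix(boxes, ncol = 4)
  if (nrow(boxes) == 0) return(integer(0))
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord) > 0) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1) break
    rest <- ord[-1]
    iou <- box_iou(boxes[i, , drop = FALSE], boxes[rest, , drop = FALSE])
    ord <- rest[iou[1, ] <= iou_thr]
  }
  keep
}

#' Anchor specification
#'
#' @param ratios height/width aspect ratios (default `c(0.5, 1, 2)`)
#' @param scales anchor scales; the square anchor side is
#'   `scale * feat_stride` pixels (default `c(8, 16, 32)`)
#' @param feat_stride feature-map stride in pixels (default 16)
#' @return an `anchor_spec` list
#' @export
anchor_spec <- function(ratios = c(0.5, 1, 2), scales = c(8, 16, 32),
                        feat_stride = 16L) {
  structure(list(ratios = ratios, scales = scales,
                 feat_stride = as.integer(feat_stride),
                 n_per_cell = length(ratios) * length(scales)),
            class = "anchor_spec")
}

#' Generate anchors over a feature map
#'
#' One anchor per (ratio, scale) pair is centered on every feature-map
#' cell's center in input-pixel coordinates. At ratio `r` the anchor keeps
#' the area of the `scale * feat_stride` square while `height/width = r`.
#' Anchors are ordered cell-major (row by row, column within row, anchor
#' within cell), matching the proposal head's channel layout.
#'
#' @param spec an [anchor_spec()]
#' @param map_h,map_w feature-map height and width (cells)
#' @return `(map_h * map_w * n_per_cell) x 4` matrix
#' @export
generate_anchors <- function(spec = anchor_spec(), map_h, map_w) {
  # anchor index order within a cell: ratio-major, scale within ratio
  base <- expand.grid(scale = spec$scales, ratio = spec$ratios)
  side <- base$scale * spec$feat_stride
  wa <- side * sqrt(1 / base$ratio)
  ha <- side * sqrt(base$ratio)
  a <- spec$n_per_cell
  cx <- (rep(seq_len(map_w) - 1, times = map_h) + 0.5) * spec$feat_stride
  cy <- (rep(seq_len(map_h) - 1, each = map_w) + 0.5) * spec$feat_stride
  n_cell <- map_h * map_w
  anchors <- matrix(0, n_cell * a, 4)
  cxr <- rep(cx, each = a)
  cyr <- rep(cy, each = a)
  war <- rep(wa, times = n_cell)
  har <- rep(ha, times = n_cell)
  anchors[, 1] <- cxr - war / 2
  anchors[, 2] <- cyr - har / 2
  anchors[, 3] <- cxr + war / 2
  anchors[, 4] <- cyr + har / 2
  anchors
}

# center/size delta encoding of target boxes against reference boxes
bbox_encode <- function(ref, gt) {
  rw <- ref[, 3] - ref[, 1]
  rh <- ref[, 4] - ref[, 2]
  rx <- ref[, 1] + rw / 2
  ry <- ref[, 2] + rh / 2
  gw <- gt[, 3] - gt[, 1]
  gh <- gt[, 4] - gt[, 2]
  gx <- gt[, 1] + gw / 2
  gy <- gt[, 2] + gh / 2
  cbind((gx - rx) / rw, (gy - ry) / rh, log(gw / rw), log(gh / rh))
}

bbox_decode <- function(ref, deltas) {
  rw <- ref[, 3] - ref[, 1]
  rh <- ref[, 4] - ref[, 2]
  rx <- ref[, 1] + rw / 2
  ry <- ref[, 2] + rh / 2
  px <- deltas[, 1] * rw + rx
  py <- deltas[, 2] * rh + ry
  pw <- exp(pmin(deltas[, 3], 4)) * rw
  ph <- exp(pmin(deltas[, 4], 4)) * rh
  cbind(px - pw / 2, py - ph / 2, px + pw / 2, py + ph / 2)
}

clip_boxes <- function(boxes, width, height) {
  boxes[, 1] <- pmin(pmax(boxes[, 1], 0), width)
  boxes[, 3] <- pmin(pmax(boxes[, 3], 0), width)
  boxes[, 2] <- pmin(pmax(boxes[, 2], 0), height)
  boxes[, 4] <- pmin(pmax(boxes[, 4], 0), height)
  boxes
}
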