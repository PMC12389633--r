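# VOC-style detection evaluation: greedy IoU matching, precision / recall /
# F1 at a fixed confidence threshold, average precision over the
# score-ranked precision-recall curve, unweighted class means, and ablation
# deltas. Detections and ground truth travel as data.frames with columns
# image, label, (score,) xmin, ymin, xmax, ymax in 0-based half-open pixel
# coordinates.

det_boxes <- function(df) {
  as.matrix(df[, c("xmin", "ymin", "xmax", "ymax"), drop = FALSE])
}

# greedy matching of one class within one image; dets must be score-sorted
greedy_match_class <- function(dets, gts, iou_thr) {
  n_gt <- nrow(gts)
  matched <- logical(n_gt)
  tp <- 0L
  fp <- 0L
  tp_flags <- logical(nrow(dets))
  if (nrow(dets) > 0) {
    ious <- if (n_gt > 0) box_iou(det_boxes(dets), det_boxes(gts)) else NULL
    for (i in seq_len(nrow(dets))) {
      best <- 0
      best_j <- 0L
      if (n_gt > 0) {
        for (j in seq_len(n_gt)) {
          if (!matched[j] && ious[i, j] >= iou_thr && ious[i, j] > best) {
            best <- ious[i, j]
            best_j <- j
          }
        }
      }
      if (best_j > 0) {
        matched[best_j] <- TRUE
        tp <- tp + 1L
        tp_flags[i] <- TRUE
      } else {
        fp <- fp + 1L
      }
    }
  }
  list(tp = tp, fp = fp, fn = n_gt - tp, tp_flags = tp_flags)
}

#' Match detections against ground truth
#'
#' Greedy per-class, per-image matching: detections are visited in
#' decreasing score order; each matches the highest-IoU unmatched ground
#' truth of its class when that IoU reaches `iou_thr` (a true positive),
#' otherwise it is a false positive (duplicate hits on an already matched
#' box included). Unmatched ground truths are false negatives.
#'
#' @param dets data.frame of detections (`image`, `label`, `score`, box
#'   columns)
#' @param gts data.frame of ground-truth boxes (`image`, `label`, box
#'   columns)
#' @param iou_thr matching IoU threshold (default 0.5)
#' @return data.frame with one row per class: `class`, `tp`, `fp`, `fn`
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  classes <- sort(unique(c(as.character(dets$label),
                           as.character(gts$label))))
  rows <- lapply(classes, function(cl) {
    dc <- dets[dets$label == cl, , drop = FALSE]
    dc <- dc[order(dc$score, decreasing = TRUE), , drop = FALSE]
    gc <- gts[gts$label == cl, , drop = FALSE]
    tp <- 0L; fp <- 0L; fn <- 0L
    for (im in unique(c(as.character(dc$image), as.character(gc$image)))) {
      m <- greedy_match_class(dc[dc$image == im, , drop = FALSE],
                              gc[gc$image == im, , drop = FALSE], iou_thr)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    data.frame(class = cl, tp = tp, fp = fp, fn = fn)
  })
  do.call(rbind, rows)
}

#' Precision, recall and F1 from match counts
#'
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)` (each 0 when its denominator is 0)
#' and `F1 = 2PR/(P+R)` (0 when `P + R = 0`).
#'
#' @param m data.frame with `tp`, `fp`, `fn` columns (e.g. from
#'   [match_detections()])
#' @return `m` with `precision`, `recall`, `f1` columns appended
#' @export
precision_recall_f1 <- function(m) {
  p <- ifelse(m$tp + m$fp > 0, m$tp / (m$tp + m$fp), 0)
  r <- ifelse(m$tp + m$fn > 0, m$tp / (m$tp + m$fn), 0)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  cbind(m, precision = p, recall = r, f1 = f1)
}

#' Average precision for one class
#'
#' Ranks the class's detections by score, matches them greedily at
#' `iou_thr`, and integrates the precision-recall curve. The default
#' all-point interpolation takes the area under the monotone (running-max
#' from the right) precision envelope; `interpolation = "11point"` averages
#' the envelope at recalls 0, 0.1, ..., 1.
#'
#' @param dets data.frame of this class's detections (`image`, `score`,
#'   box columns)
#' @param gts data.frame of this class's ground truths (`image`, box
#'   columns)
#' @param iou_thr matching threshold
#' @param interpolation `"all"` (default) or `"11point"`
#' @return AP in \[0, 1\]
#' @export
average_precision <- function(dets, gts, iou_thr = 0.5,
                              interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  n_gt <- nrow(gts)
  if (n_gt == 0) return(0)
  if (nrow(dets) == 0) return(0)
  dets <- dets[order(dets$score, decreasing = TRUE), , drop = FALSE]
  tp_flags <- logical(nrow(dets))
  for (im in unique(as.character(dets$image))) {
    sel <- which(dets$image == im)
    m <- greedy_match_class(dets[sel, , drop = FALSE],
                            gts[gts$image == im, , drop = FALSE], iou_thr)
    tp_flags[sel] <- m$tp_flags
  }
  tp_cum <- cumsum(tp_flags)
  fp_cum <- cumsum(!tp_flags)
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  # monotone envelope from the right
  env <- rev(cummax(rev(precision)))
  if (interpolation == "11point") {
    return(mean(vapply(seq(0, 1, by = 0.1), function(t) {
      ok <- recall >= t
      if (any(ok)) max(env[ok]) else 0
    }, numeric(1))))
  }
  r_prev <- c(0, head(recall, -1))
  sum((recall - r_prev) * env)
}

#' Unweighted class means of detection metrics
#'
#' @param per_class data.frame with per-class `ap`, `precision`, `recall`,
#'   `f1` columns
#' @return list with `m_ap`, `m_precision`, `m_recall`, `m_f1`, `n_classes`
#' @export
summarize_metrics <- function(per_class) {
  if (is.null(per_class) || nrow(per_class) == 0) {
    stop("no per-class metrics to summarize")
  }
  list(m_ap = mean(per_class$ap),
       m_precision = mean(per_class$precision),
       m_recall = mean(per_class$recall),
       m_f1 = mean(per_class$f1),
       n_classes = nrow(per_class))
}

#' Full evaluation of detections against ground truth
#'
#' Per class: AP from the full score-ranked detection list, plus precision,
#' recall and F1 at the single confidence threshold `score_thr`. Classes
#' are taken from the ground truth (plus any detected class).
#'
#' @inheritParams match_detections
#' @param score_thr confidence threshold for the P/R/F1 operating point
#' @param interpolation AP interpolation mode, see [average_precision()]
#' @return list with `per_class` (data.frame) and `summary` (class means)
#' @export
evaluate_detections <- function(dets, gts, iou_thr = 0.5, score_thr = 0.5,
                                interpolation = "all") {
  classes <- sort(unique(c(as.character(gts$label),
                           as.character(dets$label))))
  rows <- lapply(classes, function(cl) {
    dc <- dets[dets$label == cl, , drop = FALSE]
    gc <- gts[gts$label == cl, , drop = FALSE]
    ap <- average_precision(dc, gc, iou_thr, interpolation)
    m <- match_detections(dc[dc$score >= score_thr, , drop = FALSE], gc,
                          iou_thr)
    if (is.null(m) || nrow(m) == 0) {
      m <- data.frame(class = cl, tp = 0L, fp = 0L, fn = nrow(gc))
    }
    cbind(data.frame(class = cl, ap = ap),
          precision_recall_f1(m[, c("tp", "fp", "fn"), drop = FALSE]))
  })
  per_class <- do.call(rbind, rows)
  list(per_class = per_class, summary = summarize_metrics(per_class))
}

#' Ablation deltas between two metric sets
#'
#' Absolute differences `b - a` and relative changes `(b - a) / a` for
#' every shared numeric metric. Accepts named numeric vectors/lists or
#' data.frames sharing a `class` column. A zero baseline yields an `NA`
#' relative change.
#'
#' @param a,b baseline and comparison metrics
#' @return list with `absolute` and `relative` components
#' @export
ablation_deltas <- function(a, b) {
  if (is.data.frame(a) && is.data.frame(b)) {
    merged <- merge(a, b, by = "class", suffixes = c("_a", "_b"))
    nums <- setdiff(names(a)[vapply(a, is.numeric, TRUE)], "class")
    absolute <- data.frame(class = merged$class)
    relative <- data.frame(class = merged$class)
    for (nm in nums) {
      d <- merged[[paste0(nm, "_b")]] - merged[[paste0(nm, "_a")]]
      absolute[[nm]] <- d
      base <- merged[[paste0(nm, "_a")]]
      relative[[nm]] <- ifelse(base != 0, d / base, NA_real_)
    }
    return(list(absolute = absolute, relative = relative))
  }
  a <- unlist(a)
  b <- unlist(b)
  shared <- intersect(names(a), names(b))
  d <- b[shared] - a[shared]
  list(absolute = d,
       relative = ifelse(a[shared] != 0, d / a[shared], NA_real_))
}
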