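# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized/compiled code paths: plain nested loops.

# 2-D correlation with symmetric (mirror) border reflection
naive_filter2d_reflect <- function(img, kernel) {
  H <- nrow(img); W <- ncol(img)
  KH <- nrow(kernel); KW <- ncol(kernel)
  oh <- KH %/% 2; ow <- KW %/% 2
  out <- matrix(0, H, W)
  refl <- function(i, n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n - i + 1
    i
  }
  for (i in 1:H) for (j in 1:W) {
    acc <- 0
    for (ki in 1:KH) for (kj in 1:KW) {
      ii <- refl(i + ki - oh - 1, H)
      jj <- refl(j + kj - ow - 1, W)
      acc <- acc + img[ii, jj] * kernel[ki, kj]
    }
    out[i, j] <- acc
  }
  out
}

# 2-D correlation with zero padding on a (B,C,H,W) tensor, one output
# channel set; weights (CO, CI, KH, KW); plain loops
naive_conv4d <- function(x, w, bias = NULL, stride = 1, pad = 0) {
  d <- dim(x); wd <- dim(w)
  B <- d[1]; CI <- d[2]; H <- d[3]; W <- d[4]
  CO <- wd[1]; KH <- wd[3]; KW <- wd[4]
  HO <- (H + 2 * pad - KH) %/% stride + 1
  WO <- (W + 2 * pad - KW) %/% stride + 1
  y <- array(0, c(B, CO, HO, WO))
  for (b in 1:B) for (co in 1:CO) for (ho in 1:HO) for (wo in 1:WO) {
    acc <- if (is.null(bias)) 0 else bias[co]
    for (ci in 1:CI) for (ki in 1:KH) for (kj in 1:KW) {
      hi <- (ho - 1) * stride - pad + ki
      wi <- (wo - 1) * stride - pad + kj
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        acc <- acc + x[b, ci, hi, wi] * w[co, ci, ki, kj]
      }
    }
    y[b, co, ho, wo] <- acc
  }
  y
}

# greedy NMS by explicit pairwise loops
naive_nms <- function(boxes, scores, thr) {
  iou1 <- function(a, b) {
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
      inter
    inter / ua
  }
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  alive <- rep(TRUE, length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    if (!alive[k]) next
    keep <- c(keep, i)
    if (k < length(ord)) {
      for (m in (k + 1):length(ord)) {
        if (alive[m] && iou1(boxes[i, ], boxes[ord[m], ]) > thr) {
          alive[m] <- FALSE
        }
      }
    }
  }
  keep
}

# greedy detection/ground-truth matching by explicit loops (one class, one
# image); dets: matrix with score column first then box, already unsorted
naive_match <- function(det_boxes, det_scores, gt_boxes, thr) {
  iou1 <- function(a, b) {
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
      inter
    inter / ua
  }
  ord <- order(det_scores, decreasing = TRUE)
  used <- rep(FALSE, nrow(gt_boxes))
  tp <- 0L; fp <- 0L
  for (i in ord) {
    best <- 0; bj <- 0L
    for (j in seq_len(nrow(gt_boxes))) {
      if (used[j]) next
      v <- iou1(det_boxes[i, ], gt_boxes[j, ])
      if (v >= thr && v > best) { best <- v; bj <- j }
    }
    if (bj > 0) { used[bj] <- TRUE; tp <- tp + 1L } else fp <- fp + 1L
  }
  list(tp = tp, fp = fp, fn = nrow(gt_boxes) - tp)
}

rand_tensor <- function(b, c, h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(b * c * h * w), c(b, c, h, w))
}

rand_image <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(h * w * 3, 0, 255), c(h, w, 3))
}

# five tiny single-object training scenes, one per class (shared by the
# detector and acceptance tests)
smoke_scenes <- function(n = 5L, size = 128L,
                         size_range = c(0.35, 0.55)) {
  classes <- plantrcnn:::PLANT_CLASSES
  lapply(seq_len(n), function(i) {
    sc <- make_scene(scene_spec(
      width = size, height = size, n_objects = 1L,
      object_classes = classes[(i - 1L) %% length(classes) + 1L],
      clutter_level = 0.3, occlusion_prob = 0,
      size_range = size_range, seed = 100L + i))
    list(image = sc$image, boxes = plantrcnn:::ann_boxes(sc$annotation),
         labels = sc$annotation$objects$name)
  })
}

smoke_detector <- function(seed = 7L, scales = c(2, 4)) {
  build_detector(
    plantrcnn:::PLANT_CLASSES,
    backbone_spec(stage_blocks = c(1, 1, 1, 1), stage_mid = c(4, 8, 16, 16),
                  light = TRUE, sam_stages = rep(TRUE, 4),
                  stem_channels = 8L),
    anchor_spec(ratios = c(0.5, 1, 2), scales = scales, feat_stride = 16),
    rpn_spec(pre_nms_top_n = 600L, post_nms_top_n = 60L),
    input_size = 128L, roi_size = 4L, rpn_channels = 32L,
    head_pool = "flatten", seed = seed)
}
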