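# Two-stage detector: stride-16 backbone features feed a region proposal
# network (3x3 conv + rectifier, then 1x1 objectness and 1x1 box-delta
# heads); proposals are RoI max-pooled, pushed through the backbone's final
# stage, globally average-pooled, and classified / regressed by two linear
# heads. Class-agnostic box regression keeps the head small.

#' RPN proposal-filtering parameters
#'
#' @param nms_iou proposal suppression IoU threshold (default 0.7)
#' @param pre_nms_top_n proposals kept by score before suppression
#' @param post_nms_top_n proposals returned after suppression
#' @param min_size minimum proposal side in pixels
#' @return an `rpn_spec` list
#' @export
rpn_spec <- function(nms_iou = 0.7, pre_nms_top_n = 3000L,
                     post_nms_top_n = 300L, min_size = 1) {
  if (nms_iou <= 0 || nms_iou >= 1) stop("nms_iou must be in (0, 1)")
  structure(list(nms_iou = nms_iou,
                 pre_nms_top_n = as.integer(pre_nms_top_n),
                 post_nms_top_n = as.integer(post_nms_top_n),
                 min_size = min_size),
            class = "rpn_spec")
}

#' Training hyperparameters
#'
#' Defaults mirror the reference training configuration: 600 x 600 inputs,
#' adaptive-moment optimizer with first-moment decay 0.9, initial learning
#' rate 1e-4, batch size 4, weight decay 5e-4, 100 epochs. `steps`, when
#' given, overrides `epochs` with an absolute optimizer-step count (used by
#' the desk-scale smoke runs).
#'
#' @param input_size square input side after letterbox resize (pixels)
#' @param lr initial learning rate
#' @param batch_size images per optimizer step
#' @param epochs passes over the dataset
#' @param steps optional absolute number of optimizer steps
#' @param momentum first-moment decay of the adaptive-moment optimizer
#' @param weight_decay L2 penalty
#' @param enhance apply unsharp masking online at load time
#' @param enhance_params a [sharpen_params()]
#' @return a `train_spec` list
#' @export
train_spec <- function(input_size = 600L, lr = 1e-4, batch_size = 4L,
                       epochs = 100L, steps = NULL, momentum = 0.9,
                       weight_decay = 5e-4, enhance = TRUE,
                       enhance_params = sharpen_params()) {
  stopifnot(input_size > 0, lr >= 0, batch_size > 0, epochs > 0)
  structure(list(input_size = as.integer(input_size), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), steps = steps,
                 momentum = momentum, weight_decay = weight_decay,
                 enhance = enhance, enhance_params = enhance_params),
            class = "train_spec")
}

#' Build a two-stage detector
#'
#' @param classes character vector of foreground class names
#' @param bspec a [backbone_spec()]
#' @param aspec an [anchor_spec()]
#' @param rspec an [rpn_spec()]
#' @param input_size square training/inference input side (pixels)
#' @param roi_size RoI pooling output grid (default 7)
#' @param rpn_channels RPN intermediate channels
#' @param seed initialization seed
#' @return a detector model list
#' @export
build_detector <- function(classes,
                           bspec = backbone_spec(sam_stages = rep(TRUE, 4)),
                           aspec = anchor_spec(),
                           rspec = rpn_spec(),
                           input_size = 600L,
                           roi_size = 7L,
                           rpn_channels = 256L,
                           head_pool = c("avg", "flatten"),
                           seed = 42L) {
  head_pool <- match.arg(head_pool)
  backbone <- build_backbone(bspec, seed = seed)
  cfeat <- backbone$meta$feat_channels
  chead <- backbone$meta$head_channels
  if (head_pool == "flatten") {
    chead <- chead * head_out_hw(backbone, roi_size)^2
  }
  a <- aspec$n_per_cell
  n_cls <- length(classes) + 1L  # + background
  with_seed(seed + 1L, {
    model <- list(
      backbone = backbone,
      rpn = list(conv = nn_conv(cfeat, rpn_channels, 3L, pad = 1L),
                 cls = nn_conv(rpn_channels, 2L * a, 1L),
                 box = nn_conv(rpn_channels, 4L * a, 1L)),
      head = list(fc_cls = nn_linear(chead, n_cls),
                  fc_box = nn_linear(chead, 4L)),
      meta = list(classes = classes, aspec = aspec, rspec = rspec,
                  input_size = as.integer(input_size),
                  roi_size = as.integer(roi_size),
                  feat_stride = aspec$feat_stride,
                  rpn_channels = as.integer(rpn_channels),
                  head_pool = head_pool)
    )
    model
  })
}

## ---- geometry -----------------------------------------------------------

resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  sy <- d[1] / out_h
  sx <- d[2] / out_w
  yy <- pmin(pmax((seq_len(out_h) - 0.5) * sy - 0.5, 0), d[1] - 1)
  xx <- pmin(pmax((seq_len(out_w) - 0.5) * sx - 0.5, 0), d[2] - 1)
  y0 <- pmin(floor(yy), d[1] - 1)
  x0 <- pmin(floor(xx), d[2] - 1)
  y1 <- pmin(y0 + 1, d[1] - 1)
  x1 <- pmin(x0 + 1, d[2] - 1)
  fy <- yy - y0
  fx <- xx - x0
  out <- array(0, dim = c(out_h, out_w, if (length(d) == 3) d[3] else 1))
  img3 <- if (length(d) == 2) array(img, dim = c(d, 1)) else img
  for (ch in seq_len(dim(out)[3])) {
    m <- img3[, , ch]
    a <- m[cbind(rep(y0 + 1, times = out_w), rep(x0 + 1, each = out_h))]
    b <- m[cbind(rep(y0 + 1, times = out_w), rep(x1 + 1, each = out_h))]
    cc <- m[cbind(rep(y1 + 1, times = out_w), rep(x0 + 1, each = out_h))]
    dd <- m[cbind(rep(y1 + 1, times = out_w), rep(x1 + 1, each = out_h))]
    wfy <- rep(fy, times = out_w)
    wfx <- rep(fx, each = out_h)
    out[, , ch] <- matrix((1 - wfy) * (1 - wfx) * a + (1 - wfy) * wfx * b +
                            wfy * (1 - wfx) * cc + wfy * wfx * dd,
                          out_h, out_w)
  }
  if (length(d) == 2) out[, , 1] else out
}

# aspect-preserving resize onto a gray square canvas, centered
letterbox <- function(img, size, fill = 128) {
  d <- dim(img)
  scale <- size / max(d[1], d[2])
  nh <- max(1L, round(d[1] * scale))
  nw <- max(1L, round(d[2] * scale))
  resized <- resize_bilinear(img, nh, nw)
  canvas <- array(fill, dim = c(size, size, 3))
  py <- floor((size - nh) / 2)
  px <- floor((size - nw) / 2)
  canvas[(py + 1):(py + nh), (px + 1):(px + nw), ] <- resized
  list(image = canvas, scale = scale, pad_x = px, pad_y = py,
       orig_h = d[1], orig_w = d[2])
}

# map boxes from letterboxed coordinates back to original-image pixels
unletterbox_boxes <- function(boxes, lb) {
  out <- boxes
  out[, c(1, 3)] <- (boxes[, c(1, 3)] - lb$pad_x) / lb$scale
  out[, c(2, 4)] <- (boxes[, c(2, 4)] - lb$pad_y) / lb$scale
  clip_boxes(out, lb$orig_w, lb$orig_h)
}

image_to_tensor <- function(img) {
  d <- dim(img)
  x <- aperm(img, c(3, 1, 2)) / 127.5 - 1
  dim(x) <- c(1, d[3], d[1], d[2])
  x
}

## ---- RPN ---------------------------------------------------------------

# (1, per*A, h, w) conv output -> (h*w*A) x per matrix in anchor order
flat_anchor <- function(arr, a, per) {
  d <- dim(arr)
  s <- array(arr, dim = c(per, a, d[3], d[4]))
  m <- aperm(s, c(2, 4, 3, 1))
  dim(m) <- c(a * d[3] * d[4], per)
  m
}

unflat_anchor <- function(m, a, per, h, w) {
  dim(m) <- c(a, w, h, per)
  s <- aperm(m, c(4, 1, 3, 2))
  dim(s) <- c(1, per * a, h, w)
  s
}

#' Turn RPN outputs into scored region proposals
#'
#' Decodes box deltas against the anchors, clips to the image, drops
#' degenerate boxes, keeps the `pre_nms_top_n` highest-scoring candidates,
#' suppresses overlaps greedily at the spec's IoU threshold, and returns up
#' to `post_nms_top_n` survivors.
#'
#' @param objectness length-n foreground scores (higher = more object-like)
#' @param box_deltas n x 4 center/size deltas
#' @param anchors n x 4 anchor matrix
#' @param spec an [rpn_spec()]
#' @param im_w,im_h image width/height the proposals are clipped to
#' @return list with `boxes` (m x 4) and `scores` (length m)
#' @export
rpn_propose <- function(objectness, box_deltas, anchors, spec, im_w, im_h) {
  if (length(objectness) != nrow(anchors) ||
      nrow(box_deltas) != nrow(anchors)) {
    stop("objectness/box_deltas shapes do not match the anchor set")
  }
  boxes <- clip_boxes(bbox_decode(anchors, box_deltas), im_w, im_h)
  ok <- (boxes[, 3] - boxes[, 1]) >= spec$min_size &
    (boxes[, 4] - boxes[, 2]) >= spec$min_size
  boxes <- boxes[ok, , drop = FALSE]
  scores <- objectness[ok]
  if (nrow(boxes) == 0) {
    return(list(boxes = matrix(0, 0, 4), scores = numeric(0)))
  }
  ord <- order(scores, decreasing = TRUE)
  ord <- ord[seq_len(min(length(ord), spec$pre_nms_top_n))]
  boxes <- boxes[ord, , drop = FALSE]
  scores <- scores[ord]
  keep <- nms(boxes, scores, spec$nms_iou)
  keep <- keep[seq_len(min(length(keep), spec$post_nms_top_n))]
  list(boxes = boxes[keep, , drop = FALSE], scores = scores[keep])
}

#' RoI max pooling
#'
#' Subdivides each region of interest into an `output_size` square grid of
#' bins on the feature map and max-pools each bin. Degenerate regions are
#' clamped to at least one feature cell.
#'
#' @param features (B, C, H, W) feature array
#' @param rois n x 5 matrix: batch index (0-based) and x1, y1, x2, y2 in
#'   feature-map coordinates
#' @param output_size output grid side P
#' @return (n, C, P, P) pooled array
#' @export
roi_pool <- function(features, rois, output_size) {
  cpp_roipool_fw(features, tdim(features), rois, as.integer(output_size))$y
}

# label anchors for RPN training
assign_rpn_targets <- function(anchors, gt, im_w, im_h, pos_iou = 0.7,
                               neg_iou = 0.3, n_sample = 256L,
                               pos_frac = 0.5) {
  n <- nrow(anchors)
  inside <- which(anchors[, 1] >= 0 & anchors[, 2] >= 0 &
                    anchors[, 3] <= im_w & anchors[, 4] <= im_h)
  label <- rep(NA_integer_, n)
  iou <- box_iou(anchors[inside, , drop = FALSE], gt)
  max_iou <- apply(iou, 1, max)
  argmax <- apply(iou, 1, which.max)
  label[inside[max_iou < neg_iou]] <- 0L
  # best anchor for each ground-truth box (all ties)
  gt_best <- apply(iou, 2, max)
  for (j in seq_len(ncol(iou))) {
    if (gt_best[j] > 0) label[inside[iou[, j] == gt_best[j]]] <- 1L
  }
  label[inside[max_iou >= pos_iou]] <- 1L
  pos <- which(label == 1L)
  n_pos_max <- round(n_sample * pos_frac)
  if (length(pos) > n_pos_max) {
    drop <- sample(pos, length(pos) - n_pos_max)
    label[drop] <- NA_integer_
    pos <- which(label == 1L)
  }
  # 1:1 positive:negative sampling (minimum floor so the objectness head
  # always sees some background)
  neg <- which(label == 0L)
  n_neg <- min(length(neg), max(length(pos), 8L))
  if (length(neg) > n_neg) {
    drop <- sample(neg, length(neg) - n_neg)
    label[drop] <- NA_integer_
  }
  assigned <- rep(NA_integer_, n)
  assigned[inside] <- argmax
  targets <- matrix(0, n, 4)
  if (length(pos) > 0) {
    targets[pos, ] <- bbox_encode(anchors[pos, , drop = FALSE],
                                  gt[assigned[pos], , drop = FALSE])
  }
  list(label = label, targets = targets)
}

# choose RoIs for the classification head; the ground-truth boxes plus a
# few jittered copies are appended so positives (with diverse regression
# targets) exist from the first step
sample_rois <- function(proposals, gt, gt_labels, n_fg_classes,
                        n_rois = 128L, fg_frac = 0.25, fg_iou = 0.5,
                        n_jitter = 4L) {
  jit <- NULL
  if (n_jitter > 0 && nrow(gt) > 0) {
    for (k in seq_len(n_jitter)) {
      gw <- gt[, 3] - gt[, 1]
      gh <- gt[, 4] - gt[, 2]
      jit <- rbind(jit, cbind(gt[, 1] + rnorm(nrow(gt), 0, 0.15) * gw,
                              gt[, 2] + rnorm(nrow(gt), 0, 0.15) * gh,
                              gt[, 3] + rnorm(nrow(gt), 0, 0.15) * gw,
                              gt[, 4] + rnorm(nrow(gt), 0, 0.15) * gh))
    }
    ok <- jit[, 3] > jit[, 1] + 1 & jit[, 4] > jit[, 2] + 1
    jit <- jit[ok, , drop = FALSE]
  }
  all_rois <- rbind(proposals, jit, gt)
  iou <- box_iou(all_rois, gt)
  max_iou <- apply(iou, 1, max)
  argmax <- apply(iou, 1, which.max)
  fg <- which(max_iou >= fg_iou)
  bg <- which(max_iou < fg_iou)
  n_fg <- min(length(fg), round(n_rois * fg_frac))
  if (length(fg) > n_fg) fg <- sample(fg, n_fg)
  # 1:3 foreground:background ratio (floor keeps a background signal when
  # foreground is scarce)
  n_bg <- min(length(bg), max(3L * length(fg), 8L))
  if (length(bg) > n_bg) bg <- sample(bg, n_bg)
  keep <- c(fg, bg)
  rois <- all_rois[keep, , drop = FALSE]
  labels <- rep(n_fg_classes + 1L, length(keep))
  labels[seq_along(fg)] <- gt_labels[argmax[fg]]
  targets <- matrix(0, length(keep), 4)
  if (length(fg) > 0) {
    targets[seq_along(fg), ] <- bbox_encode(
      rois[seq_along(fg), , drop = FALSE],
      gt[argmax[fg], , drop = FALSE])
  }
  list(rois = rois, labels = labels, targets = targets,
       fg = seq_along(fg))
}

#' Two-stage detection loss
#'
#' Cross-entropy over class scores (background included as the last class)
#' plus smooth-L1 over the box deltas of foreground rows. With no
#' foreground rows the box term is zero while the classification term
#' remains defined.
#'
#' @param cls_scores n x K logit matrix
#' @param box_preds n x 4 predicted deltas
#' @param targets list with `labels` (length n, values in 1..K), `targets`
#'   (n x 4 encoded box targets) and `fg` (indices of foreground rows)
#' @return list with `cls_loss`, `box_loss`, `total`
#' @export
detection_loss <- function(cls_scores, box_preds, targets) {
  ce <- softmax_ce(cls_scores, targets$labels)
  if (length(targets$fg) > 0) {
    sl <- smooth_l1(box_preds[targets$fg, , drop = FALSE],
                    targets$targets[targets$fg, , drop = FALSE])
    box_loss <- sl$loss
  } else {
    box_loss <- 0
  }
  list(cls_loss = ce$loss, box_loss = box_loss,
       total = ce$loss + box_loss)
}

## ---- forward/backward of one training image -----------------------------

detector_step <- function(model, img, gt_boxes, gt_labels, train = TRUE) {
  meta <- model$meta
  size <- meta$input_size
  lb <- letterbox(img, size)
  gt <- gt_boxes * lb$scale
  gt[, c(1, 3)] <- gt[, c(1, 3)] + lb$pad_x
  gt[, c(2, 4)] <- gt[, c(2, 4)] + lb$pad_y
  x <- image_to_tensor(lb$image)

  ef <- extractor_fw(model$backbone, x, train)
  feat <- ef$y
  fd <- tdim(feat)
  a <- meta$aspec$n_per_cell

  rc <- conv_fw(model$rpn$conv, feat)
  rr <- relu_fw(rc$y)
  cl <- conv_fw(model$rpn$cls, rr$y)
  bx <- conv_fw(model$rpn$box, rr$y)
  logits <- flat_anchor(cl$y, a, 2L)
  deltas <- flat_anchor(bx$y, a, 4L)
  anchors <- generate_anchors(meta$aspec, fd[3], fd[4])

  rt <- assign_rpn_targets(anchors, gt, size, size)
  sampled <- which(!is.na(rt$label))
  pos <- which(rt$label == 1L)
  rpn_ce <- softmax_ce(logits[sampled, , drop = FALSE],
                       rt$label[sampled] + 1L)
  if (length(pos) > 0) {
    rpn_sl <- smooth_l1(deltas[pos, , drop = FALSE],
                        rt$targets[pos, , drop = FALSE],
                        norm = 4 * length(pos))
  } else rpn_sl <- NULL

  # proposals (gradients do not flow through box coordinates)
  p_fg <- 1 / (1 + exp(logits[, 1] - logits[, 2]))
  props <- rpn_propose(p_fg, deltas, anchors, meta$rspec, size, size)
  sr <- sample_rois(props$boxes, gt, gt_labels,
                    n_fg_classes = length(meta$classes))
  rois_feat <- cbind(0, sr$rois / meta$feat_stride)
  rp <- cpp_roipool_fw(feat, fd, rois_feat, meta$roi_size)
  ht <- head_trunk_fw(model$backbone, rp$y, train, pool = meta$head_pool)
  fc <- linear_fw(model$head$fc_cls, ht$y)
  fb <- linear_fw(model$head$fc_box, ht$y)
  head_ce <- softmax_ce(fc$y, sr$labels)
  if (length(sr$fg) > 0) {
    head_sl <- smooth_l1(fb$y[sr$fg, , drop = FALSE],
                         sr$targets[sr$fg, , drop = FALSE],
                         norm = 4 * length(sr$fg))
  } else head_sl <- NULL

  losses <- c(rpn_cls = rpn_ce$loss,
              rpn_box = if (is.null(rpn_sl)) 0 else rpn_sl$loss,
              head_cls = head_ce$loss,
              head_box = if (is.null(head_sl)) 0 else head_sl$loss)

  if (!train) return(list(losses = losses, total = sum(losses)))

  ## backward
  # head classification / regression
  dcls <- head_ce$grad
  dbox <- matrix(0, nrow(fb$y), 4)
  if (!is.null(head_sl)) dbox[sr$fg, ] <- head_sl$grad
  lc <- linear_bw(model$head$fc_cls, fc$cache, dcls)
  lbx <- linear_bw(model$head$fc_box, fb$cache, dbox)
  dfeat_head <- lc$dx + lbx$dx
  htb <- head_trunk_bw(model$backbone, ht$cache, dfeat_head)
  dpooled <- htb$dx
  dfeat_map <- cpp_roipool_bw(rp$arg, dpooled, length(feat))
  dim(dfeat_map) <- fd

  # RPN heads
  dlogits <- matrix(0, nrow(logits), 2)
  dlogits[sampled, ] <- rpn_ce$grad
  ddeltas <- matrix(0, nrow(deltas), 4)
  if (!is.null(rpn_sl)) ddeltas[pos, ] <- rpn_sl$grad
  dcl <- conv_bw(model$rpn$cls, cl$cache,
                 unflat_anchor(dlogits, a, 2L, fd[3], fd[4]))
  dbx <- conv_bw(model$rpn$box, bx$cache,
                 unflat_anchor(ddeltas, a, 4L, fd[3], fd[4]))
  drr <- relu_bw(rr$cache, dcl$dx + dbx$dx)
  drc <- conv_bw(model$rpn$conv, rc$cache, drr)

  dfeat <- dfeat_map + drc$dx
  gb <- extractor_bw(model$backbone, ef$cache, dfeat)
  gb <- g_add(gb, list(stages = htb$g))

  grads <- list(backbone = gb,
                rpn = list(conv = drc$g, cls = dcl$g, box = dbx$g),
                head = list(fc_cls = lc$g, fc_box = lbx$g))
  list(losses = losses, total = sum(losses), grads = grads)
}

#' Train a detector
#'
#' Runs the adaptive-moment optimizer over letterboxed (optionally
#' unsharp-masked) images, accumulating gradients over `batch_size` images
#' per step. Deterministic given `seed`.
#'
#' @param model a [build_detector()] model
#' @param dataset list of records, each with `image` (H x W x 3 array in
#'   \[0,255\]), `boxes` (n x 4, 0-based half-open pixels) and `labels`
#'   (character, subset of the model's classes)
#' @param spec a [train_spec()]
#' @param seed RNG seed governing sampling order
#' @return list with the trained `model` and a per-step `loss` trace
#' @export
train_detector <- function(model, dataset, spec = train_spec(),
                           seed = 42L) {
  if (length(dataset) == 0) stop("dataset is empty")
  n <- length(dataset)
  n_steps <- if (!is.null(spec$steps)) spec$steps else {
    spec$epochs * ceiling(n / spec$batch_size)
  }
  classes <- model$meta$classes
  st <- adam_state()
  trace <- data.frame(step = seq_len(n_steps), total = NA_real_,
                      rpn_cls = NA_real_, rpn_box = NA_real_,
                      head_cls = NA_real_, head_box = NA_real_)
  prepped <- lapply(dataset, function(rec) {
    img <- rec$image
    if (spec$enhance) img <- unsharp_mask(img, spec$enhance_params)
    list(image = img, boxes = rec$boxes,
         labels = match(rec$labels, classes))
  })
  if (anyNA(unlist(lapply(prepped, `[[`, "labels")))) {
    stop("dataset contains labels outside the model's class list")
  }
  with_seed(seed, {
    for (step in seq_len(n_steps)) {
      idx <- sample(n, min(spec$batch_size, n),
                    replace = spec$batch_size > n)
      grads <- NULL
      tot <- c(rpn_cls = 0, rpn_box = 0, head_cls = 0, head_box = 0)
      for (i in idx) {
        r <- detector_step(model, prepped[[i]]$image, prepped[[i]]$boxes,
                           prepped[[i]]$labels, train = TRUE)
        grads <- g_add(grads, r$grads)
        tot <- tot + r$losses
      }
      grads <- rapply(grads, function(g) g / length(idx), how = "replace")
      model <- adam_step(model, grads, st, lr = spec$lr,
                         beta1 = spec$momentum,
                         weight_decay = spec$weight_decay)
      tot <- tot / length(idx)
      trace[step, -1] <- c(sum(tot), tot)
    }
  })
  list(model = model, loss = trace)
}

#' Run detection on one image
#'
#' Letterbox-resizes the image to the model's input size, extracts
#' proposals, classifies them, applies per-class suppression, filters by
#' score, and maps the surviving boxes back to original-image pixels.
#'
#' @param model a (trained) detector
#' @param image H x W x 3 array in \[0, 255\]
#' @param score_threshold minimum class confidence kept
#' @param nms_iou test-time per-class suppression threshold
#' @param max_dets cap on returned detections
#' @return data.frame with `label`, `score`, `xmin`, `ymin`, `xmax`,
#'   `ymax` (0-based half-open pixel coordinates)
#' @export
predict_detector <- function(model, image, score_threshold = 0.5,
                             nms_iou = 0.3, max_dets = 100L,
                             batch_stats = TRUE, refine_steps = 1L) {
  meta <- model$meta
  size <- meta$input_size
  lb <- letterbox(image, size)
  x <- image_to_tensor(lb$image)
  feat <- extractor_fw(model$backbone, x,
                       train = if (batch_stats) "batch" else FALSE)$y
  fd <- tdim(feat)
  a <- meta$aspec$n_per_cell

  rr <- relu_fw(conv_fw(model$rpn$conv, feat)$y)$y
  logits <- flat_anchor(conv_fw(model$rpn$cls, rr)$y, a, 2L)
  deltas <- flat_anchor(conv_fw(model$rpn$box, rr)$y, a, 4L)
  anchors <- generate_anchors(meta$aspec, fd[3], fd[4])
  p_fg <- 1 / (1 + exp(logits[, 1] - logits[, 2]))
  props <- rpn_propose(p_fg, deltas, anchors, meta$rspec, size, size)
  empty <- data.frame(label = character(0), score = numeric(0),
                      xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0))
  if (nrow(props$boxes) == 0) return(empty)

  # head pass, optionally iterated: the regressed boxes of one pass become
  # the RoIs of the next (iterative bounding-box refinement)
  rois <- props$boxes
  for (it in seq_len(1L + max(0L, refine_steps))) {
    rois_feat <- cbind(0, rois / meta$feat_stride)
    pooled <- cpp_roipool_fw(feat, fd, rois_feat, meta$roi_size)$y
    hfeat <- head_trunk_fw(model$backbone, pooled,
                           train = if (batch_stats) "batch" else FALSE,
                           pool = meta$head_pool)$y
    scores <- linear_fw(model$head$fc_cls, hfeat)$y
    box_d <- linear_fw(model$head$fc_box, hfeat)$y
    boxes <- clip_boxes(bbox_decode(rois, box_d), size, size)
    rois <- boxes
  }
  prob <- exp(scores - apply(scores, 1, max))
  prob <- prob / rowSums(prob)

  out <- list()
  for (c in seq_along(meta$classes)) {
    sc <- prob[, c]
    keep <- which(sc >= score_threshold &
                    (boxes[, 3] - boxes[, 1]) > 0 &
                    (boxes[, 4] - boxes[, 2]) > 0)
    if (length(keep) == 0) next
    k <- nms(boxes[keep, , drop = FALSE], sc[keep], nms_iou)
    kept <- keep[k]
    mapped <- unletterbox_boxes(boxes[kept, , drop = FALSE], lb)
    out[[length(out) + 1]] <- data.frame(
      label = meta$classes[c], score = sc[kept],
      xmin = mapped[, 1], ymin = mapped[, 2],
      xmax = mapped[, 3], ymax = mapped[, 4])
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$score, decreasing = TRUE), , drop = FALSE]
  res <- res[res$xmax > res$xmin & res$ymax > res$ymin, , drop = FALSE]
  if (nrow(res) > max_dets) res <- res[seq_len(max_dets), , drop = FALSE]
  rownames(res) <- NULL
  res
}
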