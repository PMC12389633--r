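test_that("anchor generation follows the printed configuration", {
  sp <- anchor_spec()  # ratios [0.5, 1, 2], scales [8, 16, 32], stride 16
  expect_identical(sp$n_per_cell, 9L)
  a <- generate_anchors(sp, 38, 38)
  expect_identical(nrow(a), 38L * 38L * 9L)  # 12,996

  # ratio 1, scale 16, stride 16 -> a 256 x 256 anchor
  a1 <- generate_anchors(sp, 1, 1)
  widths <- a1[, 3] - a1[, 1]
  heights <- a1[, 4] - a1[, 2]
  expect_equal(widths[5], 256)
  expect_equal(heights[5], 256)

  # constant area per scale, aspect ratio h/w = r
  expect_equal(heights / widths,
               rep(c(0.5, 0.5, 0.5, 1, 1, 1, 2, 2, 2)))
  expect_equal(widths * heights,
               rep(c(128, 256, 512)^2, times = 3))

  # anchors are centered on cell centers
  a2 <- generate_anchors(anchor_spec(ratios = 1, scales = 1,
                                     feat_stride = 16), 2, 2)
  centers <- cbind((a2[, 1] + a2[, 3]) / 2, (a2[, 2] + a2[, 4]) / 2)
  expect_equal(centers, cbind(c(8, 24, 8, 24), c(8, 8, 24, 24)))
})

test_that("greedy suppression matches the brute-force oracle", {
  # duplicates collapse, disjoint boxes survive
  b <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10), c(20, 20, 30, 30))
  expect_identical(sort(nms(b, c(0.9, 0.8, 0.7), 0.7)), c(1L, 3L))

  disj <- rbind(c(0, 0, 5, 5), c(10, 10, 15, 15), c(20, 0, 25, 5))
  expect_identical(sort(nms(disj, c(0.3, 0.2, 0.1), 0.5)), 1:3)

  for (rep in 1:10) {
    set.seed(100 + rep)
    n <- sample(5:50, 1)
    x1 <- runif(n, 0, 80); y1 <- runif(n, 0, 80)
    boxes <- cbind(x1, y1, x1 + runif(n, 5, 40), y1 + runif(n, 5, 40))
    scores <- runif(n)
    expect_identical(nms(boxes, scores, 0.5),
                     naive_nms(boxes, scores, 0.5))
  }
})

test_that("proposal filtering clips, suppresses and truncates", {
  sp <- anchor_spec(ratios = 1, scales = c(2, 4), feat_stride = 16)
  anchors <- generate_anchors(sp, 4, 4)
  n <- nrow(anchors)
  set.seed(7)
  obj <- runif(n)
  deltas <- matrix(rnorm(4 * n, sd = 0.2), n, 4)
  pr <- rpn_propose(obj, deltas, anchors, rpn_spec(post_nms_top_n = 10L),
                    64, 64)
  expect_lte(nrow(pr$boxes), 10)
  expect_true(all(pr$boxes[, c(1, 3)] >= 0 & pr$boxes[, c(1, 3)] <= 64))
  expect_true(all(pr$boxes[, c(2, 4)] >= 0 & pr$boxes[, c(2, 4)] <= 64))
  expect_true(!is.unsorted(rev(pr$scores)))

  expect_error(rpn_propose(obj[-1], deltas, anchors, rpn_spec(), 64, 64),
               "match the anchor set")
})

test_that("RoI pooling matches the per-bin max oracle", {
  x <- rand_tensor(1, 2, 8, 8, seed = 8)

  # whole map to a 1 x 1 grid is the global per-channel max
  y1 <- roi_pool(x, cbind(0, 0, 0, 8, 8), 1L)
  expect_equal(y1[1, 1, 1, 1], max(x[1, 1, , ]))
  expect_equal(y1[1, 2, 1, 1], max(x[1, 2, , ]))

  # RoI equal to the map with matching output size is the identity
  y8 <- roi_pool(x, cbind(0, 0, 0, 8, 8), 8L)
  expect_equal(array(y8, dim(x)), x)

  # 2 x 2 output: max over each quadrant
  y2 <- roi_pool(x, cbind(0, 0, 0, 8, 8), 2L)
  for (c in 1:2) {
    expect_equal(y2[1, c, 1, 1], max(x[1, c, 1:4, 1:4]))
    expect_equal(y2[1, c, 2, 1], max(x[1, c, 5:8, 1:4]))
    expect_equal(y2[1, c, 1, 2], max(x[1, c, 1:4, 5:8]))
    expect_equal(y2[1, c, 2, 2], max(x[1, c, 5:8, 5:8]))
  }

  # degenerate RoI clamps to one cell instead of erroring
  yd <- roi_pool(x, cbind(0, 3, 3, 3, 3), 1L)
  expect_equal(yd[1, 1, 1, 1], x[1, 1, 4, 4])
})

test_that("detection losses have their closed-form values", {
  # near-one-hot prediction: vanishing classification loss
  logits <- matrix(c(50, 0, 0, 0, 50, 0), 2, 3, byrow = TRUE)
  tg <- list(labels = c(1L, 2L), targets = matrix(0, 2, 4), fg = integer(0))
  l <- detection_loss(logits, matrix(0, 2, 4), tg)
  expect_lt(l$cls_loss, 1e-10)
  expect_identical(l$box_loss, 0)

  # uniform scores over 6 classes: ln 6 per sample
  lu <- detection_loss(matrix(0, 4, 6), matrix(0, 4, 4),
                       list(labels = c(1L, 3L, 5L, 6L),
                            targets = matrix(0, 4, 4), fg = integer(0)))
  expect_equal(lu$cls_loss, log(6), tolerance = 1e-12)

  # matching deltas: zero box loss; mismatch: positive
  tgt <- matrix(rnorm(8), 2, 4)
  lb <- detection_loss(matrix(0, 2, 3), tgt,
                       list(labels = c(1L, 2L), targets = tgt, fg = 1:2))
  expect_identical(lb$box_loss, 0)
  lb2 <- detection_loss(matrix(0, 2, 3), tgt + 1,
                        list(labels = c(1L, 2L), targets = tgt, fg = 1:2))
  expect_gt(lb2$box_loss, 0)
  expect_equal(lb2$total, lb2$cls_loss + lb2$box_loss)
})

test_that("box encode/decode round-trips", {
  set.seed(9)
  ref <- cbind(runif(6, 0, 40), runif(6, 0, 40),
               runif(6, 50, 90), runif(6, 50, 90))
  gt <- ref + matrix(rnorm(24, sd = 3), 6, 4)
  gt[, 3] <- pmax(gt[, 3], gt[, 1] + 2)
  gt[, 4] <- pmax(gt[, 4], gt[, 2] + 2)
  dec <- plantrcnn:::bbox_decode(ref, plantrcnn:::bbox_encode(ref, gt))
  expect_equal(dec, unname(gt), tolerance = 1e-10)
})

test_that("training is deterministic and a zero learning rate is inert", {
  recs <- smoke_scenes(2)
  model <- smoke_detector(seed = 21)

  sp0 <- train_spec(input_size = 128L, lr = 0, batch_size = 1L,
                    steps = 1L, weight_decay = 0, enhance = FALSE)
  fit0 <- train_detector(model, recs, sp0, seed = 5)
  expect_identical(fit0$model$rpn$conv$p$w, model$rpn$conv$p$w)
  expect_identical(fit0$model$backbone$stem$conv$p$w,
                   model$backbone$stem$conv$p$w)

  sp <- train_spec(input_size = 128L, lr = 1e-3, batch_size = 1L,
                   steps = 3L, enhance = FALSE)
  f1 <- train_detector(model, recs, sp, seed = 6)
  f2 <- train_detector(model, recs, sp, seed = 6)
  expect_identical(f1$loss$total, f2$loss$total)
  expect_identical(f1$model$head$fc_cls$p$w, f2$model$head$fc_cls$p$w)

  expect_error(train_detector(model, list(), sp), "empty")
})

test_that("a short run reduces the training loss", {
  recs <- smoke_scenes(5)
  model <- smoke_detector(seed = 31)
  sp <- train_spec(input_size = 128L, lr = 1e-3, batch_size = 1L,
                   steps = 15L, enhance = TRUE)
  fit <- train_detector(model, recs, sp, seed = 32)
  expect_lt(mean(tail(fit$loss$total, 3)), fit$loss$total[1])
})

test_that("prediction respects its output contract", {
  recs <- smoke_scenes(1)
  model <- smoke_detector(seed = 41)

  # nothing can reach a score threshold of 1
  d1 <- predict_detector(model, recs[[1]]$image, score_threshold = 1.0)
  expect_identical(nrow(d1), 0L)

  # untrained model, threshold 0: all boxes inside the image
  d0 <- predict_detector(model, recs[[1]]$image, score_threshold = 0)
  if (nrow(d0) > 0) {
    expect_true(all(d0$xmin >= 0 & d0$ymin >= 0))
    expect_true(all(d0$xmax <= 128 & d0$ymax <= 128))
    expect_true(all(d0$xmin < d0$xmax & d0$ymin < d0$ymax))
    expect_true(all(d0$score >= 0 & d0$score <= 1))
  }

  # boxes from a letterboxed wide image map back into the unpadded region
  wide <- rand_image(60, 120, seed = 42) # letterboxed with vertical padding
  dw <- predict_detector(model, wide, score_threshold = 0)
  if (nrow(dw) > 0) {
    expect_true(all(dw$ymin >= 0 & dw$ymax <= 60))
    expect_true(all(dw$xmin >= 0 & dw$xmax <= 120))
  }
})

test_that("letterboxing and its inverse are consistent", {
  lb <- plantrcnn:::letterbox(array(100, c(60, 120, 3)), 128)
  expect_identical(dim(lb$image), c(128L, 128L, 3L))
  expect_equal(lb$scale, 128 / 120)
  # a box spanning the full resized content maps back to the full image
  content <- cbind(lb$pad_x, lb$pad_y, lb$pad_x + 120 * lb$scale,
                   lb$pad_y + 60 * lb$scale)
  back <- plantrcnn:::unletterbox_boxes(content, lb)
  expect_equal(as.vector(back), c(0, 0, 120, 60), tolerance = 1e-9)
})

test_that("convolution backward matches numeric gradients", {
  ns <- asNamespace("plantrcnn")
  set.seed(51)
  l <- ns$nn_conv(3, 4, 3, stride = 2, pad = 1, groups = 1)
  x <- rand_tensor(1, 3, 5, 5)
  fw <- ns$conv_fw(l, x)
  tgt <- array(rnorm(length(fw$y)), dim(fw$y))
  bw <- ns$conv_bw(l, fw$cache, fw$y - tgt)
  loss_w <- function(w) {
    l2 <- l
    l2$p$w <- array(w, dim(l$p$w))
    sum((ns$conv_fw(l2, x)$y - tgt)^2) / 2
  }
  eps <- 1e-5
  idx <- sample(length(l$p$w), 10)
  for (i in idx) {
    w1 <- as.vector(l$p$w); w2 <- w1
    w1[i] <- w1[i] + eps; w2[i] <- w2[i] - eps
    expect_equal(bw$g$w[i], (loss_w(w1) - loss_w(w2)) / (2 * eps),
                 tolerance = 1e-5)
  }
})
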