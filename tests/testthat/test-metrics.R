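dets_df <- function(image, score, boxes) {
  n <- length(score)
  data.frame(image = rep(image, length.out = n),
             label = rep("x", n), score = score,
             xmin = boxes[, 1], ymin = boxes[, 2],
             xmax = boxes[, 3], ymax = boxes[, 4])
}

test_that("greedy matching implements the duplicate rule", {
  gt <- data.frame(image = "a", label = "x",
                   xmin = c(0, 50), ymin = c(0, 50),
                   xmax = c(10, 60), ymax = c(10, 60))
  # perfect detections: one per ground truth
  d <- cbind(dets_df("a", c(0.9, 0.8), rbind(c(0, 0, 10, 10),
                                             c(50, 50, 60, 60))))
  m <- match_detections(d, gt)
  expect_identical(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))

  # two detections on one ground truth: 1 tp + 1 fp (duplicate rule)
  d2 <- dets_df("a", c(0.9, 0.8), rbind(c(0, 0, 10, 10), c(1, 1, 10, 10)))
  m2 <- match_detections(d2, gt)
  expect_identical(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 1L))

  # label and image identity are respected
  d3 <- d
  d3$label <- "y"
  m3 <- match_detections(d3, gt)
  expect_identical(m3$tp[m3$class == "x"], 0L)
  d4 <- d
  d4$image <- "b"
  m4 <- match_detections(d4, gt)
  expect_identical(c(m4$tp, m4$fn), c(0L, 2L))
})

test_that("matching equals the brute-force oracle on random fixtures", {
  for (rep in 1:12) {
    set.seed(400 + rep)
    ng <- sample(1:4, 1)
    nd <- sample(0:8, 1)
    gx <- runif(ng, 0, 60); gy <- runif(ng, 0, 60)
    gtb <- cbind(gx, gy, gx + runif(ng, 8, 25), gy + runif(ng, 8, 25))
    if (nd > 0) {
      dx <- runif(nd, 0, 60); dy <- runif(nd, 0, 60)
      db <- cbind(dx, dy, dx + runif(nd, 8, 25), dy + runif(nd, 8, 25))
      sc <- runif(nd)
    } else {
      db <- matrix(0, 0, 4); sc <- numeric(0)
    }
    want <- naive_match(db, sc, gtb, 0.5)
    gt <- data.frame(image = "a", label = "x", xmin = gtb[, 1],
                     ymin = gtb[, 2], xmax = gtb[, 3], ymax = gtb[, 4])
    got <- match_detections(dets_df("a", sc, db), gt, 0.5)
    expect_identical(c(got$tp, got$fp, got$fn),
                     c(want$tp, want$fp, as.integer(want$fn)))
    # tp + fn equals the ground-truth count
    expect_identical(got$tp + got$fn, ng)
  }
})

test_that("precision/recall/F1 reproduce the printed operating points", {
  # P = 75.00%, R = 66.67% -> F1 = 0.71
  m1 <- data.frame(tp = 8, fp = 8 / 0.75 - 8, fn = 8 / (2 / 3) - 8)
  r1 <- precision_recall_f1(m1)
  expect_equal(round(r1$f1, 2), 0.71)

  # P = 32.00%, R = 80.00% -> F1 = 0.46
  f2 <- 2 * 0.32 * 0.80 / (0.32 + 0.80)
  m2 <- data.frame(tp = 8, fp = 17, fn = 2)  # P = 8/25 = .32, R = .8
  r2 <- precision_recall_f1(m2)
  expect_equal(r2$precision, 0.32)
  expect_equal(r2$recall, 0.8)
  expect_equal(r2$f1, f2)
  expect_equal(round(r2$f1, 2), 0.46)

  # P = R implies F1 = P; zero denominators give zeros
  m3 <- data.frame(tp = 3, fp = 1, fn = 1)
  r3 <- precision_recall_f1(m3)
  expect_equal(r3$f1, r3$precision)
  r0 <- precision_recall_f1(data.frame(tp = 0, fp = 0, fn = 0))
  expect_identical(c(r0$precision, r0$recall, r0$f1), c(0, 0, 0))
})

test_that("average precision integrates the ranked PR curve", {
  gt3 <- data.frame(image = "a",
                    xmin = c(0, 30, 60), ymin = c(0, 30, 60),
                    xmax = c(10, 40, 70), ymax = c(10, 40, 70))

  # one gt, one perfect detection
  gt1 <- gt3[1, ]
  expect_equal(average_precision(dets_df("a", 0.9,
                                         rbind(c(0, 0, 10, 10))), gt1), 1)

  # no detections
  none <- data.frame(image = character(0), label = character(0),
                     score = numeric(0), xmin = numeric(0),
                     ymin = numeric(0), xmax = numeric(0),
                     ymax = numeric(0))
  expect_equal(average_precision(none, gt3), 0)

  # 5 detections / 3 gts, hand-integrated oracle: ranks are
  # tp, fp, tp, fp(duplicate), tp -> AP = (1 + 2/3 + 3/5) / 3 = 34/45
  d5 <- dets_df("a", c(0.9, 0.8, 0.7, 0.6, 0.5),
                rbind(c(0, 0, 10, 10),      # hits gt1
                      c(100, 100, 110, 110), # miss
                      c(30, 30, 40, 40),    # hits gt2
                      c(1, 1, 10, 10),      # duplicate on gt1
                      c(60, 60, 70, 70)))   # hits gt3
  expect_equal(average_precision(d5, gt3), 34 / 45, tolerance = 1e-12)
  expect_equal(average_precision(d5, gt3, interpolation = "11point"),
               (4 * 1 + 3 * (2 / 3) + 4 * 0.6) / 11, tolerance = 1e-12)

  # invariant to monotone score transforms
  d5b <- d5
  d5b$score <- d5$score^3 + 1
  expect_equal(average_precision(d5b, gt3), average_precision(d5, gt3))

  # a trailing false positive never increases AP
  worse <- rbind(d5, dets_df("a", 0.1, rbind(c(200, 200, 210, 210))))
  expect_lte(average_precision(worse, gt3), average_precision(d5, gt3))
  expect_gte(average_precision(d5, gt3), 0)
  expect_lte(average_precision(d5, gt3), 1)
})

test_that("class means reproduce the printed summary rows", {
  per_class <- data.frame(
    class = c("Acanthus mollis", "Cirsium eriophorum", "Gentiana lutea",
              "Hyacinthoides non-scripta", "Urospermum dalechampii"),
    ap = c(78.60, 68.33, 53.30, 46.91, 72.74) / 100,
    precision = c(40.00, 75.00, 20.59, 30.77, 30.00) / 100,
    recall = c(80.00, 66.67, 53.85, 61.54, 66.67) / 100,
    f1 = c(0.53, 0.71, 0.30, 0.41, 0.41))
  s <- summarize_metrics(per_class)
  expect_equal(round(100 * s$m_ap, 2), 63.98)
  expect_equal(round(100 * s$m_precision, 2), 39.27)
  expect_equal(round(100 * s$m_recall, 2), 65.75)
  expect_equal(round(s$m_f1, 2), 0.47)
  expect_identical(s$n_classes, 5L)

  # means stay within the per-class range
  expect_gte(s$m_ap, min(per_class$ap))
  expect_lte(s$m_ap, max(per_class$ap))

  one <- summarize_metrics(per_class[2, ])
  expect_equal(one$m_ap, per_class$ap[2])
  expect_error(summarize_metrics(per_class[0, ]), "summarize")
})

test_that("ablation deltas reproduce the printed improvements", {
  base <- c(ap = 51.66)
  new <- c(ap = 78.60)
  d <- ablation_deltas(base, new)
  expect_equal(unname(d$absolute["ap"]), 26.94)

  # identical summaries: zero deltas
  z <- ablation_deltas(c(a = 1, b = 2), c(a = 1, b = 2))
  expect_true(all(z$absolute == 0))

  # 16.42 -> 36.37 is a 121.5% relative increase
  r <- ablation_deltas(c(ap = 16.42), c(ap = 36.37))
  expect_equal(round(100 * unname(r$relative["ap"]), 1), 121.5)

  # zero baseline yields an undefined relative change
  u <- ablation_deltas(c(ap = 0), c(ap = 33.57))
  expect_true(is.na(u$relative["ap"]))

  # data.frame flavor merges by class
  a_df <- data.frame(class = c("x", "y"), ap = c(10, 20))
  b_df <- data.frame(class = c("x", "y"), ap = c(15, 18))
  dd <- ablation_deltas(a_df, b_df)
  expect_equal(dd$absolute$ap, c(5, -2))
  expect_equal(dd$relative$ap, c(0.5, -0.1))
})
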