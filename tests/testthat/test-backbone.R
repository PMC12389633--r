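test_that("bottleneck blocks obey the shape contract", {
  set.seed(1)
  blk <- make_bottleneck(256, 64, 256, stride = 1L, light = TRUE)
  x <- rand_tensor(1, 256, 8, 8)
  y <- bottleneck_forward(blk, x)
  expect_identical(dim(y), c(1L, 256L, 8L, 8L))

  blk2 <- make_bottleneck(256, 64, 256, stride = 2L, light = TRUE)
  x2 <- rand_tensor(1, 256, 14, 14)
  expect_identical(dim(bottleneck_forward(blk2, x2)), c(1L, 256L, 7L, 7L))

  expect_error(make_bottleneck(64, 16, 128), "4 \\* mid_ch")
  expect_error(make_bottleneck(64, 16, 64, stride = 3), "stride")
  expect_error(bottleneck_forward(blk, rand_tensor(1, 64, 8, 8)),
               "channels")
})

test_that("a zeroed expansion branch reduces to the rectified shortcut", {
  set.seed(2)
  blk <- make_bottleneck(16, 4, 16, stride = 1L, light = TRUE)
  blk$conv3$p$w[] <- 0
  x <- rand_tensor(1, 16, 5, 5)
  y <- bottleneck_forward(blk, x, train = TRUE)
  expect_equal(y, x * (x > 0), tolerance = 1e-12)
})

test_that("closed-form parameter counts match the stated arithmetic", {
  # conv weights only: standard vs depthwise 3x3
  expect_identical(
    bottleneck_param_count(256, 64, 256, light = FALSE,
                           include_norm = FALSE),
    256 * 64 + 64 * 64 * 9 + 64 * 256)
  expect_identical(
    bottleneck_param_count(256, 64, 256, light = TRUE,
                           include_norm = FALSE),
    256 * 64 + 64 * 9 + 64 * 256)
  expect_identical(bottleneck_param_count(256, 64, 256, light = FALSE,
                                          include_norm = FALSE), 69632)
  expect_identical(bottleneck_param_count(256, 64, 256, light = TRUE,
                                          include_norm = FALSE), 33344)

  # light is strictly smaller whenever mid >= 2
  for (mid in c(2, 8, 64, 512)) {
    expect_lt(bottleneck_param_count(4 * mid, mid, 4 * mid, light = TRUE),
              bottleneck_param_count(4 * mid, mid, 4 * mid, light = FALSE))
  }
})

test_that("formula and instantiated census agree across a spec grid", {
  set.seed(3)
  grid <- expand.grid(mid = c(2, 4, 8), stride = c(1L, 2L),
                      light = c(TRUE, FALSE), sam = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    in_ch <- 4 * g$mid  # stage-interior convention
    blk <- make_bottleneck(in_ch, g$mid, 4 * g$mid, stride = g$stride,
                           light = g$light, use_sam = g$sam)
    expect_identical(count_params(blk)$total_params,
                     bottleneck_param_count(in_ch, g$mid, 4 * g$mid,
                                            stride = g$stride,
                                            light = g$light,
                                            use_sam = g$sam),
                     info = paste(unlist(g), collapse = "/"))
  }
})

test_that("the assembled extractor is a stride-16 map", {
  spec <- backbone_spec(stage_blocks = c(1, 1, 1, 1),
                        stage_mid = c(2, 2, 2, 2), stem_channels = 4L)
  bb <- build_backbone(spec, seed = 4)
  x <- array(rnorm(3 * 600 * 600, sd = 0.5), c(1, 3, 600, 600))
  y <- backbone_forward(bb, x)
  expect_identical(dim(y)[3:4], c(38L, 38L))  # 600 -> 300 -> 150 -> 75 -> 38
  expect_identical(dim(y)[2], 4L * spec$stage_mid[3])

  x2 <- array(0, c(1, 3, 320, 320))
  expect_identical(dim(backbone_forward(bb, x2))[3:4], c(20L, 20L))
})

test_that("light backbones shed most convolution parameters", {
  light <- backbone_param_count(backbone_spec(light = TRUE),
                                include_norm = FALSE)
  std <- backbone_param_count(backbone_spec(light = FALSE),
                              include_norm = FALSE)
  expect_lt(light / std, 0.60)

  # attention adds exactly 2*7*7 + 1 parameters per gated block
  base <- backbone_spec(sam_stages = rep(FALSE, 4))
  gated <- backbone_spec(sam_stages = rep(TRUE, 4))
  n_blocks <- sum(base$stage_blocks)
  expect_identical(backbone_param_count(gated) - backbone_param_count(base),
                   n_blocks * (2 * 7 * 7 + 1))

  # closed form equals the instantiated census on a small spec
  sp <- backbone_spec(stage_blocks = c(2, 2, 2, 2),
                      stage_mid = c(2, 4, 4, 8), stem_channels = 4L,
                      sam_stages = c(TRUE, FALSE, TRUE, FALSE))
  bb <- build_backbone(sp, seed = 5)
  expect_identical(count_params(bb)$total_params, backbone_param_count(sp))
})

test_that("initialization and forward are deterministic under a seed", {
  sp <- backbone_spec(stage_blocks = c(1, 1, 1, 1),
                      stage_mid = c(2, 2, 2, 2), stem_channels = 4L)
  b1 <- build_backbone(sp, seed = 11)
  b2 <- build_backbone(sp, seed = 11)
  expect_identical(b1$stem$conv$p$w, b2$stem$conv$p$w)
  x <- rand_tensor(1, 3, 64, 64, seed = 12)
  expect_identical(backbone_forward(b1, x), backbone_forward(b2, x))
  b3 <- build_backbone(sp, seed = 13)
  expect_false(identical(b1$stem$conv$p$w, b3$stem$conv$p$w))
})
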