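# Depthwise-separable "light" bottleneck blocks and their assembly into a
# ResNet-50-layout feature extractor. The extractor (stem + stages 1-3) has
# total stride 16; stage 4 is kept separate and runs on RoI-pooled features
# as the classification head's trunk.

#' Construct a (light) bottleneck block
#'
#' Sequence: 1x1 compression convolution + norm + rectifier, 3x3
#' convolution + norm + rectifier (depthwise, i.e. one filter per channel,
#' when `light = TRUE`; stride lives here), 1x1 pointwise expansion
#' convolution + norm, residual addition (1x1 projected shortcut when the
#' shape changes), rectifier. Optionally a split spatial-attention module
#' gates the block output. Convolutions carry no bias (the following norm
#' absorbs it).
#'
#' @param in_ch,mid_ch,out_ch channel counts; `out_ch` must equal
#'   `4 * mid_ch` (ResNet expansion convention)
#' @param stride 1 or 2, applied on the 3x3 convolution
#' @param light use a depthwise 3x3 convolution (default TRUE)
#' @param use_sam gate the block output with split spatial attention
#' @param sam_groups,sam_kernel attention-module hyperparameters
#' @return a bottleneck module
#' @export
make_bottleneck <- function(in_ch, mid_ch, out_ch, stride = 1L,
                            light = TRUE, use_sam = FALSE,
                            sam_groups = 1L, sam_kernel = 7L) {
  if (out_ch != 4 * mid_ch) stop("out_ch must equal 4 * mid_ch")
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  m <- list(meta = list(in_ch = in_ch, mid_ch = mid_ch, out_ch = out_ch,
                        stride = as.integer(stride), light = light,
                        use_sam = use_sam,
                        project = (stride != 1L || in_ch != out_ch)),
            conv1 = nn_conv(in_ch, mid_ch, 1L, bias = FALSE),
            bn1 = nn_bn(mid_ch),
            conv2 = nn_conv(mid_ch, mid_ch, 3L, stride = stride, pad = 1L,
                            groups = if (light) mid_ch else 1L,
                            bias = FALSE),
            bn2 = nn_bn(mid_ch),
            conv3 = nn_conv(mid_ch, out_ch, 1L, bias = FALSE),
            bn3 = nn_bn(out_ch))
  if (m$meta$project) {
    m$down_conv <- nn_conv(in_ch, out_ch, 1L, stride = stride, bias = FALSE)
    m$down_bn <- nn_bn(out_ch)
  }
  if (use_sam) m$sam <- make_split_sam(sam_groups, sam_kernel)
  m
}

bottleneck_fw <- function(m, x, train = FALSE) {
  c1 <- conv_fw(m$conv1, x)
  b1 <- bn_fw(m$bn1, c1$y, train)
  r1 <- relu_fw(b1$y)
  c2 <- conv_fw(m$conv2, r1$y)
  b2 <- bn_fw(m$bn2, c2$y, train)
  r2 <- relu_fw(b2$y)
  c3 <- conv_fw(m$conv3, r2$y)
  b3 <- bn_fw(m$bn3, c3$y, train)
  if (m$meta$project) {
    dc <- conv_fw(m$down_conv, x)
    db <- bn_fw(m$down_bn, dc$y, train)
    short <- db$y
    down_cache <- list(conv = dc$cache, bn = db$cache)
  } else {
    short <- x
    down_cache <- NULL
  }
  ro <- relu_fw(b3$y + short)
  cache <- list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                c3 = c3$cache, b3 = b3$cache, down = down_cache,
                ro = ro$cache)
  y <- ro$y
  if (!is.null(m$sam)) {
    sf <- sam_fw(m$sam, y)
    cache$sam <- sf$cache
    y <- sf$y
  }
  list(y = y, cache = cache)
}

bottleneck_bw <- function(m, cache, gy) {
  g <- list()
  if (!is.null(m$sam)) {
    sb <- sam_bw(m$sam, cache$sam, gy)
    g$sam <- sb$g
    gy <- sb$dx
  }
  gsum <- relu_bw(cache$ro, gy)
  # main branch
  b3 <- bn_bw(m$bn3, cache$b3, gsum)
  g$bn3 <- b3$g
  c3 <- conv_bw(m$conv3, cache$c3, b3$dx)
  g$conv3 <- c3$g
  r2 <- relu_bw(cache$r2, c3$dx)
  b2 <- bn_bw(m$bn2, cache$b2, r2)
  g$bn2 <- b2$g
  c2 <- conv_bw(m$conv2, cache$c2, b2$dx)
  g$conv2 <- c2$g
  r1 <- relu_bw(cache$r1, c2$dx)
  b1 <- bn_bw(m$bn1, cache$b1, r1)
  g$bn1 <- b1$g
  c1 <- conv_bw(m$conv1, cache$c1, b1$dx)
  g$conv1 <- c1$g
  dx <- c1$dx
  # shortcut branch
  if (m$meta$project) {
    db <- bn_bw(m$down_bn, cache$down$bn, gsum)
    g$down_bn <- db$g
    dc <- conv_bw(m$down_conv, cache$down$conv, db$dx)
    g$down_conv <- dc$g
    dx <- dx + dc$dx
  } else {
    dx <- dx + gsum
  }
  list(dx = dx, g = g)
}

#' Run a bottleneck block forward
#'
#' @param block a [make_bottleneck()] module
#' @param x (B, C, H, W) array with C equal to the block's input channels
#' @param train use batch statistics in the normalization layers
#' @return output feature map
#' @export
bottleneck_forward <- function(block, x, train = FALSE) {
  bottleneck_fw(block, x, train)$y
}

#' Closed-form parameter count of a bottleneck block
#'
#' Counts learnable parameters from the block hyperparameters alone:
#' convolution weights (no biases) plus, optionally, two affine parameters
#' per normalized channel, the projection shortcut when present, and the
#' attention module's `2*k*k + 1` parameters when `use_sam`.
#'
#' @inheritParams make_bottleneck
#' @param include_norm include the normalization affine parameters
#' @return exact learnable-parameter count
#' @export
bottleneck_param_count <- function(in_ch, mid_ch, out_ch, stride = 1L,
                                   light = TRUE, use_sam = FALSE,
                                   include_norm = TRUE, sam_kernel = 7L) {
  project <- (stride != 1L || in_ch != out_ch)
  conv <- in_ch * mid_ch +
    (if (light) mid_ch * 9 else mid_ch * mid_ch * 9) +
    mid_ch * out_ch +
    (if (project) in_ch * out_ch else 0)
  norm <- if (include_norm) {
    2 * (mid_ch + mid_ch + out_ch) + (if (project) 2 * out_ch else 0)
  } else 0
  sam <- if (use_sam) 2 * sam_kernel * sam_kernel + 1 else 0
  conv + norm + sam
}

#' Backbone specification
#'
#' @param stage_blocks blocks per stage (default the ResNet-50 layout
#'   `c(3, 4, 6, 3)`)
#' @param stage_mid bottleneck mid-channel widths per stage (output widths
#'   are 4x these)
#' @param light use depthwise-separable (light) bottlenecks
#' @param sam_stages logical per-stage flags: gate each block of the stage
#'   with split spatial attention
#' @param stem_channels stem convolution output channels
#' @param sam_groups,sam_kernel attention hyperparameters
#' @return a `backbone_spec` list
#' @export
backbone_spec <- function(stage_blocks = c(3L, 4L, 6L, 3L),
                          stage_mid = c(64L, 128L, 256L, 512L),
                          light = TRUE,
                          sam_stages = rep(FALSE, length(stage_blocks)),
                          stem_channels = 64L,
                          sam_groups = 1L, sam_kernel = 7L) {
  if (length(stage_blocks) != length(stage_mid)) {
    stop("stage_blocks and stage_mid must have equal length")
  }
  if (length(sam_stages) != length(stage_blocks)) {
    stop("sam_stages must carry one flag per stage")
  }
  if (any(stage_blocks < 1) || any(stage_mid < 1)) {
    stop("stage lists must be positive")
  }
  structure(list(stage_blocks = as.integer(stage_blocks),
                 stage_mid = as.integer(stage_mid),
                 light = light, sam_stages = sam_stages,
                 stem_channels = as.integer(stem_channels),
                 sam_groups = as.integer(sam_groups),
                 sam_kernel = as.integer(sam_kernel),
                 feat_stride = 16L),
            class = "backbone_spec")
}

#' Build the feature-extraction backbone
#'
#' Stem (7x7 stride-2 convolution + norm + rectifier + 3x3 stride-2 max
#' pool) followed by bottleneck stages. Stages 1-3 form the stride-16
#' feature extractor consumed by the region proposal network; the final
#' stage is kept as a separate trunk for the RoI head. Initialization is
#' deterministic under `seed`.
#'
#' @param spec a [backbone_spec()]
#' @param seed integer seed for weight initialization
#' @return a backbone model list with `stem`, `stages`, and `meta`
#' @export
build_backbone <- function(spec = backbone_spec(), seed = 42L) {
  stopifnot(inherits(spec, "backbone_spec"))
  with_seed(seed, {
    model <- list(stem = list(conv = nn_conv(3L, spec$stem_channels, 7L,
                                             stride = 2L, pad = 3L,
                                             bias = FALSE),
                              bn = nn_bn(spec$stem_channels)),
                  stages = list(), meta = list())
    in_ch <- spec$stem_channels
    n_stage <- length(spec$stage_blocks)
    for (s in seq_len(n_stage)) {
      mid <- spec$stage_mid[s]
      out <- 4L * mid
      blocks <- list()
      for (b in seq_len(spec$stage_blocks[s])) {
        stride <- if (s > 1 && b == 1) 2L else 1L
        blocks[[paste0("b", b)]] <-
          make_bottleneck(in_ch, mid, out, stride = stride,
                          light = spec$light,
                          use_sam = isTRUE(spec$sam_stages[s]),
                          sam_groups = spec$sam_groups,
                          sam_kernel = spec$sam_kernel)
        in_ch <- out
      }
      model$stages[[paste0("s", s)]] <- blocks
    }
    model$meta <- list(spec = spec,
                       n_extract_stages = n_stage - 1L,
                       feat_channels = 4L * spec$stage_mid[n_stage - 1L],
                       head_channels = 4L * spec$stage_mid[n_stage])
    model
  })
}

# stride-16 extractor: stem + all stages but the last
extractor_fw <- function(model, x, train = FALSE) {
  cache <- list()
  c1 <- conv_fw(model$stem$conv, x)
  b1 <- bn_fw(model$stem$bn, c1$y, train)
  r1 <- relu_fw(b1$y)
  mp <- maxpool_fw(r1$y, 3L, 2L, 1L)
  cache$stem <- list(conv = c1$cache, bn = b1$cache, relu = r1$cache,
                     pool = mp$cache)
  h <- mp$y
  cache$stages <- list()
  for (s in seq_len(model$meta$n_extract_stages)) {
    sn <- paste0("s", s)
    cache$stages[[sn]] <- list()
    for (bn in names(model$stages[[sn]])) {
      bf <- bottleneck_fw(model$stages[[sn]][[bn]], h, train)
      cache$stages[[sn]][[bn]] <- bf$cache
      h <- bf$y
    }
  }
  list(y = h, cache = cache)
}

extractor_bw <- function(model, cache, gy) {
  g <- list(stages = list())
  for (s in rev(seq_len(model$meta$n_extract_stages))) {
    sn <- paste0("s", s)
    g$stages[[sn]] <- list()
    for (bn in rev(names(model$stages[[sn]]))) {
      bb <- bottleneck_bw(model$stages[[sn]][[bn]],
                          cache$stages[[sn]][[bn]], gy)
      g$stages[[sn]][[bn]] <- bb$g
      gy <- bb$dx
    }
  }
  dpool <- maxpool_bw(cache$stem$pool, gy)
  drelu <- relu_bw(cache$stem$relu, dpool)
  b1 <- bn_bw(model$stem$bn, cache$stem$bn, drelu)
  c1 <- conv_bw(model$stem$conv, cache$stem$conv, b1$dx)
  g$stem <- list(bn = b1$g, conv = c1$g)
  g
}

#' Extract stride-16 features
#'
#' @param model a [build_backbone()] model
#' @param x (B, 3, H, W) array
#' @param train use batch statistics in normalization layers
#' @return (B, C_feat, H/16, W/16) feature map
#' @export
backbone_forward <- function(model, x, train = FALSE) {
  extractor_fw(model, x, train)$y
}

# last stage on RoI-pooled features, then either global average pooling
# (ResNet convention) or flattening (classic detection-head convention,
# keeps the spatial layout the box regressor needs)
head_trunk_fw <- function(model, pooled, train = FALSE, pool = "avg") {
  sn <- paste0("s", model$meta$n_extract_stages + 1L)
  cache <- list()
  h <- pooled
  for (bn in names(model$stages[[sn]])) {
    bf <- bottleneck_fw(model$stages[[sn]][[bn]], h, train)
    cache[[bn]] <- bf$cache
    h <- bf$y
  }
  d <- tdim(h)
  if (pool == "avg") {
    feat <- apply(h, c(1, 2), mean)
    if (is.null(dim(feat))) feat <- matrix(feat, nrow = d[1])
  } else {
    feat <- h
    dim(feat) <- c(d[1], d[2] * d[3] * d[4])
  }
  list(y = feat, cache = list(blocks = cache, hdim = d, pool = pool))
}

head_trunk_bw <- function(model, cache, gy) {
  sn <- paste0("s", model$meta$n_extract_stages + 1L)
  d <- cache$hdim
  if (cache$pool == "avg") {
    gh <- array(rep(gy / (d[3] * d[4]), times = d[3] * d[4]), dim = d)
  } else {
    gh <- gy
    dim(gh) <- d
  }
  g <- list()
  for (bn in rev(names(model$stages[[sn]]))) {
    bb <- bottleneck_bw(model$stages[[sn]][[bn]], cache$blocks[[bn]], gh)
    g[[bn]] <- bb$g
    gh <- bb$dx
  }
  list(g = setNames(list(g), sn), dx = gh)
}

# spatial side of the head-trunk output for a given RoI grid size
head_out_hw <- function(model, roi_size) {
  sn <- paste0("s", model$meta$n_extract_stages + 1L)
  h <- roi_size
  for (blk in model$stages[[sn]]) {
    h <- (h + 2 - 3) %/% blk$meta$stride + 1
  }
  h
}

#' Closed-form parameter count of a whole backbone
#'
#' Sums the stem and every block's [bottleneck_param_count()], without
#' instantiating any tensors.
#'
#' @inheritParams build_backbone
#' @param include_norm include normalization affine parameters
#' @return total learnable-parameter count
#' @export
backbone_param_count <- function(spec = backbone_spec(),
                                 include_norm = TRUE) {
  total <- 7 * 7 * 3 * spec$stem_channels +
    (if (include_norm) 2 * spec$stem_channels else 0)
  in_ch <- spec$stem_channels
  for (s in seq_along(spec$stage_blocks)) {
    mid <- spec$stage_mid[s]
    out <- 4L * mid
    for (b in seq_len(spec$stage_blocks[s])) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      total <- total + bottleneck_param_count(
        in_ch, mid, out, stride = stride, light = spec$light,
        use_sam = isTRUE(spec$sam_stages[s]),
        include_norm = include_norm, sam_kernel = spec$sam_kernel)
      in_ch <- out
    }
  }
  total
}
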